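#' Genome layout
#'
#' An ordered chromosome coordinate frame: chromosome names, lengths in bp,
#' and which chromosomes are sex chromosomes. Sliding windows are built on
#' the autosomes only, and the variant filter can drop sex-chromosome
#' records (the G1xG2 backcross scheme cannot maintain X- or Y-linked
#' recessive mutations).
#'
#' @param chrom Character vector of chromosome names (unique, ordered).
#' @param length Numeric vector of chromosome lengths in bp (all > 0).
#' @param sex_chromosomes Character vector of names to treat as sex
#'   chromosomes; they need not all be present in `chrom`.
#' @return An object of class `genome_layout`: a data frame with columns
#'   `chrom` and `length` and an attribute `sex_chromosomes`.
#' @examples
#' genome_layout(c("1", "2", "X"), c(50e6, 40e6, 30e6))
#' @export
genome_layout <- function(chrom, length, sex_chromosomes = c("X", "Y", "chrX", "chrY")) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    stop("'chrom' and 'length' must have equal length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  attr(out, "sex_chromosomes") <- as.character(sex_chromosomes)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("Genome layout:", nrow(x), "chromosomes,",
      format(sum(x$length) / 1e6, digits = 5), "Mb total\n")
  cat("Autosomes:", paste(autosomes(x)$chrom, collapse = " "), "\n")
  sx <- intersect(x$chrom, attr(x, "sex_chromosomes"))
  if (length(sx)) cat("Sex chromosomes present:", paste(sx, collapse = " "), "\n")
  invisible(x)
}

#' Autosomal subset of a layout
#'
#' @param layout A [genome_layout()].
#' @return A `genome_layout` containing only the non-sex chromosomes.
#' @export
autosomes <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  keep <- !(layout$chrom %in% attr(layout, "sex_chromosomes"))
  out <- layout[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sex_chromosomes") <- attr(layout, "sex_chromosomes")
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Desk-scale mouse-like genome layout
#'
#' The simulator's default coordinate frame: `n_chrom` equal-length
#' autosomes. The default (19 x 130 Mb = 2.47 Gb) approximates the scale of
#' the mouse autosomal genome while keeping simulations fast.
#'
#' @param n_chrom Number of autosomes.
#' @param chrom_length Length of each autosome in bp.
#' @return A [genome_layout()].
#' @export
desk_layout <- function(n_chrom = 19, chrom_length = 130e6) {
  genome_layout(as.character(seq_len(n_chrom)), rep(chrom_length, n_chrom))
}

#' Read or write a chromosome-length table
#'
#' Two-column TSV: chromosome name and length in bp, no header.
#'
#' @param path File path.
#' @param sex_chromosomes Passed to [genome_layout()].
#' @return `read_genome_tsv()` returns a [genome_layout()];
#'   `write_genome_tsv()` returns `path` invisibly.
#' @export
read_genome_tsv <- function(path, sex_chromosomes = c("X", "Y", "chrX", "chrY")) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric"),
                           col.names = c("chrom", "length"))
  genome_layout(tab$chrom, tab$length, sex_chromosomes = sex_chromosomes)
}

#' @rdname read_genome_tsv
#' @param layout A [genome_layout()] to write.
#' @export
write_genome_tsv <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(layout[, c("chrom", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
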