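#' Functional annotation categories
#'
#' The closed set of per-variant functional categories (refGene-style
#' classes). Exon-resident categories are those a whole-exome capture would
#' query; the "damaging" subset is what the candidate caller keeps.
#'
#' @format Character vectors.
#' @name categories
NULL

#' @rdname categories
#' @export
VARIANT_CATEGORIES <- c("exonic_nonsynonymous", "exonic_synonymous",
                        "stopgain", "stoploss", "splicing", "intronic",
                        "intergenic", "utr", "unknown")

#' @rdname categories
#' @export
EXON_RESIDENT_CATEGORIES <- c("exonic_nonsynonymous", "exonic_synonymous",
                              "stopgain", "stoploss", "splicing")

#' @rdname categories
#' @export
DAMAGING_CATEGORIES <- c("exonic_nonsynonymous", "stopgain", "stoploss",
                         "splicing")

variant_columns <- c("chrom", "pos", "ref", "alt", "alts", "qual", "depth",
                     "alt_depth", "naf", "gene", "category", "aa_change",
                     "in_known_db", "in_repeat", "multiallelic")

#' Construct a variant table
#'
#' One row per biallelic SNV call from a pooled sample. `naf` (non-reference
#' allele frequency) is `alt_depth / depth`, the fraction of pooled reads
#' carrying the first alternate allele; it is `NA` when `depth` is 0.
#' Multiallelic records are retained and flagged at construction time; the
#' filter stage, not the parser, removes them.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Reference and first alternate allele.
#' @param qual Phred-scaled site quality.
#' @param depth Total read depth (integer >= 0).
#' @param alt_depth Reads supporting the first alternate allele
#'   (0 <= alt_depth <= depth).
#' @param alts Comma-separated full ALT string (defaults to `alt`).
#' @param gene,category,aa_change Optional functional annotation; `category`
#'   must come from [VARIANT_CATEGORIES].
#' @param in_known_db,in_repeat Provenance flags.
#' @return A data frame of class `variant_table`.
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          qual = numeric(), depth = integer(),
                          alt_depth = integer(), alts = NULL,
                          gene = NA_character_, category = NA_character_,
                          aa_change = NA_character_, in_known_db = FALSE,
                          in_repeat = FALSE) {
  n <- length(pos)
  if (is.null(alts)) alts <- as.character(alt)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   alts = rep_len(as.character(alts), n),
                   qual = as.numeric(qual), depth = as.integer(depth),
                   alt_depth = as.integer(alt_depth),
                   naf = rep_len(NA_real_, n),
                   gene = rep_len(as.character(gene), n),
                   category = rep_len(as.character(category), n),
                   aa_change = rep_len(as.character(aa_change), n),
                   in_known_db = rep_len(as.logical(in_known_db), n),
                   in_repeat = rep_len(as.logical(in_repeat), n),
                   multiallelic = rep_len(FALSE, n),
                   stringsAsFactors = FALSE)
  df$multiallelic <- grepl(",", df$alts, fixed = TRUE)
  df$naf <- ifelse(df$depth > 0, df$alt_depth / df$depth, NA_real_)
  validate_variant_table(df)
}

validate_variant_table <- function(df) {
  missing <- setdiff(variant_columns, names(df))
  if (length(missing)) {
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(df$depth < 0, na.rm = TRUE)) stop("depth must be >= 0")
  bad <- df$alt_depth < 0 | df$alt_depth > df$depth
  if (any(bad, na.rm = TRUE)) {
    stop("alt_depth outside [0, depth] at row ", which(bad)[1L])
  }
  known_cat <- is.na(df$category) | df$category %in% VARIANT_CATEGORIES
  if (!all(known_cat)) {
    stop("unknown annotation category: ",
         df$category[which(!known_cat)[1L]])
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table:", nrow(x), "SNVs on",
      length(unique(x$chrom)), "chromosomes\n")
  if (nrow(x)) {
    cat("  mean depth ", format(mean(x$depth), digits = 3),
        ", mean NAF ", format(mean(x$naf, na.rm = TRUE), digits = 3),
        ", annotated ", sum(!is.na(x$category)), "\n", sep = "")
  }
  NextMethod()
}

# keep the class when subsetting rows
#' @export
`[.variant_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(variant_columns %in% names(out))) {
    class(out) <- c("variant_table", "data.frame")
  }
  out
}

#' Check genome-order sorting of a variant table
#'
#' @param variants A [variant_table()].
#' @param layout A [genome_layout()] giving the chromosome order.
#' @return Logical scalar.
#' @export
is_genome_sorted <- function(variants, layout) {
  ord <- match(variants$chrom, layout$chrom)
  if (anyNA(ord)) return(FALSE)
  all(diff(ord * 1e10 + variants$pos) >= 0)
}

genome_order <- function(variants, layout = NULL) {
  if (is.null(layout)) {
    order(variants$chrom, variants$pos)
  } else {
    order(match(variants$chrom, layout$chrom), variants$pos)
  }
}
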