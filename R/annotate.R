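#' Annotate variants against an exon model
#'
#' Assigns a functional category to each variant from interval overlap with
#' an exon model:
#'
#' * inside an exon: the coding consequence cannot be determined from
#'   intervals alone (no codon logic in this package), so the category is
#'   `"unknown"` with the exon's gene label attached;
#' * within `splice_margin` bp outside an exon boundary: `"splicing"`;
#' * otherwise `"intronic"` when inside a gene body (span of a gene's
#'   exons), else `"intergenic"`.
#'
#' A pre-attached annotation (from VCF INFO keys or the simulator) always
#' wins: only variants with a missing `category` are annotated. Variants on
#' chromosomes absent from the exon model become `"intergenic"` with a
#' warning.
#'
#' @param variants A [variant_table()].
#' @param exons An [interval_set()] carrying gene labels (4-column BED), or
#'   a data frame with columns chrom, start, end, name (0-based half-open).
#' @param splice_margin Splice-site margin in bp outside an exon
#'   (default 10).
#' @return The variant table with `category` and `gene` filled in.
#' @export
annotate_by_intervals <- function(variants, exons, splice_margin = 10) {
  variants <- validate_variant_table(variants)
  ex <- exon_features(exons)
  todo <- which(is.na(variants$category))
  if (!length(todo)) return(variants)

  unknown_chrom <- !(variants$chrom[todo] %in% unique(ex$chrom))
  if (any(unknown_chrom)) {
    warning(sum(unknown_chrom),
            " variant(s) on chromosomes absent from the exon model; ",
            "annotated as intergenic")
  }

  gene_body <- NULL
  if (nrow(ex)) {
    gene_body <- do.call(rbind, lapply(split(ex, paste(ex$chrom, ex$name)),
      function(d) data.frame(chrom = d$chrom[1], start = min(d$start),
                             end = max(d$end), name = d$name[1],
                             stringsAsFactors = FALSE)))
  }

  for (i in todo) {
    pos0 <- variants$pos[i] - 1
    e <- ex[ex$chrom == variants$chrom[i], , drop = FALSE]
    if (!nrow(e)) {
      variants$category[i] <- "intergenic"
      next
    }
    inside <- pos0 >= e$start & pos0 < e$end
    if (any(inside)) {
      variants$category[i] <- "unknown"  # exonic, coding consequence unresolved
      variants$gene[i] <- e$name[which(inside)[1L]]
      next
    }
    # distance outside the nearest exon edge, in bp (1 = immediately adjacent)
    dist <- pmin(ifelse(pos0 < e$start, e$start - pos0, Inf),
                 ifelse(pos0 >= e$end, pos0 - e$end + 1, Inf))
    if (min(dist) <= splice_margin) {
      variants$category[i] <- "splicing"
      variants$gene[i] <- e$name[which.min(dist)]
      next
    }
    gb <- gene_body[gene_body$chrom == variants$chrom[i], , drop = FALSE]
    in_body <- pos0 >= gb$start & pos0 < gb$end
    if (any(in_body)) {
      variants$category[i] <- "intronic"
      variants$gene[i] <- gb$name[which(in_body)[1L]]
    } else {
      variants$category[i] <- "intergenic"
    }
  }
  variants
}

exon_features <- function(exons) {
  if (inherits(exons, "interval_set")) {
    if (!is.null(exons$features)) return(exons$features)
    rows <- lapply(names(exons$intervals), function(ch) {
      d <- exons$intervals[[ch]]
      if (!nrow(d)) return(NULL)
      data.frame(chrom = ch, start = d$start, end = d$end,
                 name = NA_character_, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), name = character())
    }
    return(out)
  }
  stopifnot(is.data.frame(exons),
            all(c("chrom", "start", "end") %in% names(exons)))
  if (is.null(exons$name)) exons$name <- NA_character_
  exons[, c("chrom", "start", "end", "name")]
}
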