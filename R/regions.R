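#' Call candidate mapping regions from scored windows
#'
#' A window qualifies when it holds at least `cfg$min_snps` variants and
#' its metric strictly exceeds the threshold: `hom_pct` (percent scale,
#' 0-100) for the homozygosity criterion, `avg_naf` (fraction, 0-1) for the
#' NAF criterion. Qualifying windows that overlap or abut on one chromosome
#' are merged into a single region spanning their minimum start to maximum
#' end (no gap bridging), so every region is at least one window long. The
#' candidate recombinant interval containing a recessive mutation shows up
#' as such a region.
#'
#' @param windows A scored window table from [score_windows()].
#' @param criterion `"homozygosity"` or `"naf"`.
#' @param threshold Strict lower threshold on the criterion metric; in
#'   `[0, 100]` for homozygosity, `[0, 1]` for naf.
#' @param cfg A [window_config()] (supplies `min_snps`).
#' @param variants Optional [variant_table()]; when given, each region's
#'   `n_snps` counts the variants inside it, otherwise the count is `NA`.
#' @return A data frame of class `region_table` with columns chrom, start,
#'   end, criterion, n_windows, n_snps, peak_value, sorted by descending
#'   peak value with ties in genome order. No qualifying window gives zero
#'   rows.
#' @export
find_regions <- function(windows, criterion = c("homozygosity", "naf"),
                         threshold, cfg = window_config(), variants = NULL) {
  criterion <- match.arg(criterion)
  metric <- if (criterion == "homozygosity") windows$hom_pct else windows$avg_naf
  if (criterion == "homozygosity") {
    stopifnot(threshold >= 0, threshold <= 100)
  } else {
    stopifnot(threshold >= 0, threshold <= 1)
  }
  ok <- !is.na(metric) & windows$n_snps >= cfg$min_snps & metric > threshold
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), criterion = character(),
                      n_windows = integer(), n_snps = integer(),
                      peak_value = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("region_table", "data.frame")
  if (!any(ok)) return(empty)

  q <- windows[ok, , drop = FALSE]
  q$metric <- metric[ok]
  chrom_order <- unique(windows$chrom)
  out <- list()
  for (ch in unique(q$chrom)) {
    d <- q[q$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = d$start + 1, end = d$end)
    red <- IRanges::reduce(ir)  # merges overlapping and abutting windows
    # reduced intervals are sorted and disjoint: locate each window's group
    grp <- findInterval(d$start + 1, IRanges::start(red))
    for (g in seq_along(red)) {
      member <- grp == g
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = IRanges::start(red)[g] - 1,
        end = as.numeric(IRanges::end(red)[g]),
        criterion = criterion,
        n_windows = sum(member),
        n_snps = NA_integer_,
        peak_value = max(d$metric[member]),
        stringsAsFactors = FALSE)
    }
  }
  regions <- do.call(rbind, out)
  if (!is.null(variants)) {
    regions$n_snps <- vapply(seq_len(nrow(regions)), function(i) {
      sum(variants$chrom == regions$chrom[i] &
            variants$pos - 1 >= regions$start[i] &
            variants$pos - 1 < regions$end[i])
    }, integer(1))
  }
  ord <- order(-regions$peak_value, match(regions$chrom, chrom_order),
               regions$start)
  regions <- regions[ord, , drop = FALSE]
  rownames(regions) <- NULL
  class(regions) <- c("region_table", "data.frame")
  regions
}

#' Write regions as BED
#'
#' 5-column BED: chrom, start, end, name (the calling criterion), score
#' (peak metric value x 1000, integer).
#'
#' @param regions A region table from [find_regions()].
#' @param path Output file path.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d", regions$chrom,
                     as.integer(regions$start), as.integer(regions$end),
                     regions$criterion,
                     as.integer(round(regions$peak_value * 1000))), path)
  invisible(path)
}
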