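#' Sliding-window configuration
#'
#' Windows of `size` bp advance by `step` bp along each autosome, so
#' consecutive windows overlap by `size - step` bp. 2, 5, 10 and 20 Mb are
#' the usual window sizes for pooled mapping at ~1 induced variant per Mb;
#' 20 Mb with a 1 Mb step is the default. `hom_naf_threshold` is the pooled
#' NAF at or above which a variant is classed homozygous, and `min_snps`
#' guards region calling against variant-sparse windows (prominent in
#' whole-exome mode).
#'
#' @param size Window size in bp.
#' @param step Step between window starts in bp (0 < step <= size).
#' @param hom_naf_threshold Homozygote classification threshold on NAF,
#'   inclusive (default 0.9).
#' @param min_snps Minimum variants for a window to be eligible for region
#'   calling.
#' @return An object of class `window_config`.
#' @export
window_config <- function(size = 20e6, step = 1e6, hom_naf_threshold = 0.9,
                          min_snps = 5) {
  stopifnot(step > 0, step <= size, hom_naf_threshold > 0,
            hom_naf_threshold <= 1, min_snps >= 0)
  structure(list(size = size, step = step,
                 hom_naf_threshold = hom_naf_threshold,
                 min_snps = min_snps),
            class = "window_config")
}

#' Classify pooled zygosity from NAF
#'
#' A variant is classed homozygous when its pooled non-reference allele
#' frequency is at or above the threshold, heterozygous otherwise. The
#' classification is only meaningful for covered sites: a zero-depth
#' variant is an error (the default filtering cascade guarantees depth >=
#' 5 upstream).
#'
#' @param variants A [variant_table()] (or a numeric NAF vector).
#' @param hom_naf_threshold Inclusive threshold on NAF (default 0.9).
#' @return Character vector, `"hom"` or `"het"`.
#' @export
call_zygosity <- function(variants, hom_naf_threshold = 0.9) {
  naf <- if (is.data.frame(variants)) {
    if (any(variants$depth == 0)) {
      stop("cannot classify zygosity at depth 0; filter variants first")
    }
    variants$naf
  } else {
    as.numeric(variants)
  }
  if (anyNA(naf)) stop("cannot classify zygosity for undefined NAF")
  ifelse(naf >= hom_naf_threshold, "hom", "het")
}

#' Build sliding windows over the autosomes
#'
#' Per autosome, windows start at 0, step, 2*step, ... while `start + size`
#' does not exceed the chromosome; when those windows do not reach the
#' chromosome end, one final truncated window `[last_start + step, length)`
#' is appended, so every autosomal bp is covered by at least one window. A
#' chromosome shorter than the window size yields the single window
#' `[0, length)`.
#'
#' @param layout A [genome_layout()]; sex chromosomes are skipped.
#' @param cfg A [window_config()].
#' @return A data frame of class `window_table` with columns chrom, start,
#'   end (0-based half-open) and empty metric columns `n_snps`,
#'   `hom_count`, `hom_pct`, `avg_naf`.
#' @export
make_windows <- function(layout, cfg = window_config()) {
  stopifnot(inherits(layout, "genome_layout"), inherits(cfg, "window_config"))
  auto <- autosomes(layout)
  rows <- lapply(seq_len(nrow(auto)), function(i) {
    L <- auto$length[i]
    starts <- seq(0, max(0, L - cfg$size), by = cfg$step)
    ends <- pmin(starts + cfg$size, L)
    if (max(ends) < L) {
      starts <- c(starts, starts[length(starts)] + cfg$step)
      ends <- c(ends, L)
    }
    data.frame(chrom = auto$chrom[i], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$n_snps <- NA_integer_
  out$hom_count <- NA_integer_
  out$hom_pct <- NA_real_
  out$avg_naf <- NA_real_
  class(out) <- c("window_table", "data.frame")
  out
}

#' Score windows with the three mapping metrics
#'
#' For every window, over the variants whose 0-based position (`pos - 1`)
#' falls inside it: the variant count (`n_snps`), the number classed
#' homozygous (`hom_count`, NAF at or above `cfg$hom_naf_threshold`), the
#' homozygote percentage (`hom_pct`), and the mean pooled NAF (`avg_naf`).
#' Windows with no variants keep undefined (`NA`) metrics and are excluded
#' from region calling. Implemented with cumulative sums over
#' position-sorted variants; a naive per-window rescan gives identical
#' results and serves as the test oracle.
#'
#' @param variants A filtered [variant_table()] with defined NAF.
#' @param windows A window table from [make_windows()].
#' @param cfg A [window_config()].
#' @return The window table with metrics filled in.
#' @export
score_windows <- function(variants, windows, cfg = window_config()) {
  variants <- validate_variant_table(variants)
  if (anyNA(variants$naf)) {
    stop("variants with undefined NAF (depth 0); filter before scoring")
  }
  hom <- variants$naf >= cfg$hom_naf_threshold
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    vi <- which(variants$chrom == ch)
    if (!length(vi)) {
      windows$n_snps[wi] <- 0L
      next
    }
    ord <- vi[order(variants$pos[vi])]
    pos0 <- variants$pos[ord] - 1
    cum_hom <- cumsum(hom[ord])
    cum_naf <- cumsum(variants$naf[ord])
    # number of variants with pos0 < x
    below <- function(x) findInterval(x - 0.5, pos0)
    lo <- below(windows$start[wi])
    hi <- below(windows$end[wi])
    n <- hi - lo
    windows$n_snps[wi] <- n
    at <- function(cum, k) ifelse(k > 0, cum[pmax(k, 1L)], 0)
    windows$hom_count[wi] <- as.integer(at(cum_hom, hi) - at(cum_hom, lo))
    windows$avg_naf[wi] <- ifelse(n > 0,
                                  (at(cum_naf, hi) - at(cum_naf, lo)) / n,
                                  NA_real_)
  }
  windows$n_snps <- as.integer(windows$n_snps)
  windows$hom_count[windows$n_snps == 0L] <- NA_integer_
  windows$hom_pct <- ifelse(windows$n_snps > 0,
                            100 * windows$hom_count / windows$n_snps,
                            NA_real_)
  windows
}

#' Write scored windows as TSV
#'
#' @param windows A scored window table.
#' @param path Output file path.
#' @export
write_windows_tsv <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
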