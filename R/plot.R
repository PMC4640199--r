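#' Plot genome-wide mapping tracks
#'
#' Draws the three window metrics (average NAF, homozygote count,
#' homozygote percentage) as stacked panels across the concatenated
#' autosomes, chromosomes alternately shaded. Windows with undefined
#' metrics (no variants) are dropped rather than drawn as zero, to avoid
#' fake troughs. The output device is chosen by file extension (`.png` or
#' `.pdf`).
#'
#' @param windows A scored window table from [score_windows()].
#' @param layout A [genome_layout()] (autosome order and lengths).
#' @param path Output image file path.
#' @return Invisibly, a list with `path` and `peak_chrom`, the chromosome
#'   holding the maximal window per metric.
#' @export
plot_tracks <- function(windows, layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  auto <- autosomes(layout)
  offset <- c(0, cumsum(auto$length))[seq_len(nrow(auto))]
  names(offset) <- auto$chrom

  if (grepl("\\.pdf$", path, ignore.case = TRUE)) {
    grDevices::pdf(path, width = 10, height = 6)
  } else {
    grDevices::png(path, width = 1200, height = 700)
  }
  on.exit(grDevices::dev.off())

  metrics <- c(avg_naf = "average NAF", hom_count = "hom count",
               hom_pct = "hom percentage")
  graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))

  peak_chrom <- stats::setNames(rep(NA_character_, length(metrics)),
                                names(metrics))
  total <- sum(auto$length)
  for (m in names(metrics)) {
    keep <- !is.na(windows[[m]]) & windows$chrom %in% auto$chrom
    ylim <- switch(m, avg_naf = c(0, 1), hom_pct = c(0, 100),
                   c(0, max(1, windows[[m]][keep], na.rm = TRUE)))
    graphics::plot(NA, xlim = c(0, total), ylim = ylim, xlab = "",
                   ylab = metrics[[m]], xaxt = "n", las = 1)
    graphics::axis(1, at = offset + auto$length / 2, labels = auto$chrom,
                   tick = FALSE, cex.axis = 0.8)
    shade <- which(seq_len(nrow(auto)) %% 2 == 0)
    graphics::rect(offset[shade], ylim[1], offset[shade] + auto$length[shade],
                   ylim[2], col = "grey92", border = NA)
    if (any(keep)) {
      w <- windows[keep, , drop = FALSE]
      x <- offset[w$chrom] + (w$start + w$end) / 2
      graphics::points(x, w[[m]], pch = 16, cex = 0.4, col = "steelblue4")
      peak_chrom[m] <- w$chrom[which.max(w[[m]])]
    }
  }
  invisible(list(path = path, peak_chrom = peak_chrom))
}
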