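test_that("zygosity classification is an inclusive NAF threshold", {
  expect_equal(call_zygosity(c(1.0, 0.5, 0.9, 0.89)),
               c("hom", "het", "hom", "het"))
  v <- variant_table(chrom = "1", pos = 1L, ref = "A", alt = "T", qual = 50,
                     depth = 0L, alt_depth = 0L)
  expect_error(call_zygosity(v), "depth 0")
})

test_that("window construction follows the step arithmetic", {
  layout <- genome_layout("1", 50e6)
  cfg <- window_config(size = 20e6, step = 1e6)
  w <- make_windows(layout, cfg)
  expect_equal(nrow(w), 31L)  # floor((50 - 20) / 1) + 1
  expect_equal(c(w$start[1], w$end[1]), c(0, 20e6))
  expect_equal(c(w$start[31], w$end[31]), c(30e6, 50e6))

  one <- make_windows(genome_layout("1", 20e6), cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(0, 20e6))

  short <- make_windows(genome_layout("1", 0.4e6), cfg)
  expect_equal(nrow(short), 1L)
  expect_equal(c(short$start, short$end), c(0, 0.4e6))
})

test_that("windows cover every autosomal bp and skip sex chromosomes", {
  set.seed(5)
  for (i in 1:5) {
    layout <- genome_layout(c("1", "2", "X"),
                            c(round(runif(1, 1e6, 80e6)),
                              round(runif(1, 1e6, 80e6)), 30e6))
    cfg <- window_config(size = 10e6, step = 2e6)
    w <- make_windows(layout, cfg)
    expect_false("X" %in% w$chrom)
    for (ch in c("1", "2")) {
      d <- w[w$chrom == ch, ]
      L <- layout$length[layout$chrom == ch]
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
      expect_equal(length(ir), 1L)
      expect_equal(c(IRanges::start(ir), IRanges::end(ir)), c(1, L))
      expect_true(all(d$end <= L))
    }
  }
})

test_that("window metrics match hand computation", {
  v <- variant_table(chrom = rep("1", 4), pos = c(1e6, 2e6, 3e6, 4e6),
                     ref = "A", alt = "T", qual = 50,
                     depth = rep(10L, 4), alt_depth = c(10L, 10L, 5L, 5L))
  w <- make_windows(genome_layout("1", 20e6), window_config(size = 20e6))
  s <- score_windows(v, w)
  expect_equal(s$n_snps, 4L)
  expect_equal(s$hom_count, 2L)
  expect_equal(s$hom_pct, 50)
  expect_equal(s$avg_naf, 0.75)

  all_hom <- variant_table(chrom = rep("1", 4), pos = c(1e6, 2e6, 3e6, 4e6),
                           ref = "A", alt = "T", qual = 50,
                           depth = rep(10L, 4), alt_depth = rep(10L, 4))
  s2 <- score_windows(all_hom, w)
  expect_equal(s2$hom_count, 4L)
  expect_equal(s2$hom_pct, 100)
  expect_equal(s2$avg_naf, 1)
})

test_that("window scoring equals a naive per-window rescan", {
  set.seed(13)
  layout <- toy_layout()
  cfg <- window_config(size = 8e6, step = 3e6, min_snps = 1)
  for (rep in 1:5) {
    v <- random_variants(2000)
    w <- make_windows(layout, cfg)
    fast <- score_windows(v, w, cfg)
    slow <- naive_score_windows(v, w, cfg)
    expect_equal(fast, slow)
  }
})

test_that("total window membership matches per-variant containment counts", {
  set.seed(17)
  v <- random_variants(500)
  cfg <- window_config(size = 10e6, step = 4e6)
  w <- score_windows(v, make_windows(toy_layout(), cfg), cfg)
  per_variant <- vapply(seq_len(nrow(v)), function(i) {
    sum(w$chrom == v$chrom[i] & w$start <= v$pos[i] - 1 &
          w$end > v$pos[i] - 1)
  }, numeric(1))
  expect_equal(sum(w$n_snps), sum(per_variant))
})

test_that("qualifying windows merge into regions by span arithmetic", {
  # 6 consecutive qualifying 20 Mb windows at 1 Mb step span 25 Mb
  layout <- genome_layout("1", 60e6)
  cfg <- window_config(size = 20e6, step = 1e6, min_snps = 0)
  w <- make_windows(layout, cfg)
  w$n_snps <- 10L
  w$hom_count <- 0L
  w$hom_pct <- 10
  w$avg_naf <- 0.4
  qual_idx <- 6:11
  w$hom_pct[qual_idx] <- 95
  r <- find_regions(w, "homozygosity", 90, cfg)
  expect_equal(nrow(r), 1L)
  expect_equal(r$end - r$start, 25e6)
  expect_equal(r$start, w$start[6])
  expect_equal(r$n_windows, 6L)
  expect_equal(r$peak_value, 95)
})

test_that("background-level NAF windows yield no regions at the 0.7 cutoff", {
  layout <- genome_layout("1", 60e6)
  cfg <- window_config()
  w <- make_windows(layout, cfg)
  w$n_snps <- 20L
  w$hom_count <- 0L
  w$hom_pct <- 0
  w$avg_naf <- 0.5  # the random unlinked expectation
  expect_equal(nrow(find_regions(w, "naf", 0.7, cfg)), 0L)
  # and the threshold is strict: exactly 0.7 does not qualify
  w$avg_naf <- 0.7
  expect_equal(nrow(find_regions(w, "naf", 0.7, cfg)), 0L)
})

test_that("sparse windows are ineligible for region calling", {
  layout <- genome_layout("1", 30e6)
  cfg <- window_config(size = 20e6, step = 1e6, min_snps = 5)
  w <- make_windows(layout, cfg)
  w$n_snps <- 4L
  w$hom_count <- 4L
  w$hom_pct <- 100
  w$avg_naf <- 1
  expect_equal(nrow(find_regions(w, "homozygosity", 60, cfg)), 0L)
})

test_that("raising the region threshold never increases total region span", {
  set.seed(19)
  layout <- toy_layout()
  cfg <- window_config(size = 10e6, step = 2e6, min_snps = 1)
  v <- random_variants(3000)
  w <- score_windows(v, make_windows(layout, cfg), cfg)
  spans <- vapply(c(0.3, 0.5, 0.7, 0.9), function(thr) {
    r <- find_regions(w, "naf", thr, cfg)
    if (nrow(r)) sum(r$end - r$start) else 0
  }, numeric(1))
  expect_true(all(diff(spans) <= 0))
})

test_that("region ranking is by peak value with genome-order ties", {
  layout <- genome_layout(c("1", "2"), c(30e6, 30e6))
  cfg <- window_config(size = 10e6, step = 10e6, min_snps = 0)
  w <- make_windows(layout, cfg)
  w$n_snps <- 10L
  w$hom_count <- 0L
  w$hom_pct <- 0
  w$avg_naf <- c(0.8, 0.1, 0.1, 0.1, 0.9, 0.1)
  r <- find_regions(w, "naf", 0.7, cfg)
  expect_equal(r$chrom, c("2", "1"))  # higher peak first
  expect_equal(r$peak_value, c(0.9, 0.8))
})

test_that("track plots are written and report the spiked chromosome", {
  set.seed(29)
  layout <- toy_layout()
  cfg <- window_config(size = 10e6, step = 5e6)
  v <- random_variants(600)
  spike <- v$chrom == "2"
  v$alt_depth[spike] <- v$depth[spike]
  v$naf[spike] <- 1
  w <- score_windows(v, make_windows(layout, cfg), cfg)
  path <- tempfile(fileext = ".pdf")
  meta <- plot_tracks(w, layout, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  expect_equal(unname(meta$peak_chrom["avg_naf"]), "2")

  empty_path <- tempfile(fileext = ".pdf")
  expect_no_error(plot_tracks(make_windows(layout, cfg), layout, empty_path))
  expect_true(file.exists(empty_path))
})
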