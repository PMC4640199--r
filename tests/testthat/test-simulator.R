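small_cfg <- function(...) {
  args <- list(layout = genome_layout(c("1", "2", "3"), rep(60e6, 3)),
               seq_error = 0)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("mutation draws respect chromosome bounds and the exon fraction", {
  set.seed(51)
  cfg <- small_cfg()
  for (i in 1:5) {
    muts <- draw_mutations(cfg)
    auto <- autosomes(cfg$layout)
    expect_true(all(muts$pos >= 1))
    expect_true(all(muts$pos <= auto$length[match(muts$chrom, auto$chrom)]))
    expect_equal(sum(muts$causal), 1L)
    expect_true(muts$category[muts$causal] %in% DAMAGING_CATEGORIES)
  }
  # exon_fraction 0 with a fixed causal position: only the causal variant
  # is exon-resident
  cfg0 <- small_cfg(exon_fraction = 0, causal_choice = c("2", 30e6))
  muts <- draw_mutations(cfg0)
  exonic <- muts$category %in% EXON_RESIDENT_CATEGORIES
  expect_equal(sum(exonic), 1L)
  expect_true(muts$causal[exonic])
})

test_that("the variant count is Poisson at the configured rate", {
  set.seed(53)
  cfg <- small_cfg()  # 180 Mb x 1.2/Mb = 216 expected
  counts <- replicate(200, nrow(draw_mutations(cfg)))
  lambda <- 1.2 * 180
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("meiosis without recombination copies one parent exactly", {
  set.seed(57)
  cfg <- small_cfg(recomb_rate = 0)
  muts <- draw_mutations(cfg)
  hap_a <- rep(c(TRUE, FALSE), length.out = nrow(muts))
  hap_b <- !hap_a
  g <- meiosis(hap_a, hap_b, muts, cfg)
  for (ch in unique(muts$chrom)) {
    i <- muts$chrom == ch
    expect_true(identical(g[i], hap_a[i]) || identical(g[i], hap_b[i]))
  }
})

test_that("meiosis transmits each variant from a heterozygote at frequency 1/2", {
  set.seed(59)
  cfg <- small_cfg()
  muts <- draw_mutations(cfg)
  hap_mut <- rep(TRUE, nrow(muts))
  hap_wt <- rep(FALSE, nrow(muts))
  n_gam <- 400
  carried <- matrix(FALSE, nrow(muts), n_gam)
  for (g in seq_len(n_gam)) {
    carried[, g] <- meiosis(hap_mut, hap_wt, muts, cfg)
  }
  freq <- rowMeans(carried)
  se <- sqrt(0.25 / n_gam)
  # genome-wide average transmission (variants within a chromosome are
  # correlated, so the effective sample is ~ gametes x chromosomes)
  expect_lt(abs(mean(freq) - 0.5), 3 * sqrt(0.25 / (3 * n_gam)) + 0.01)
  expect_true(all(abs(freq - 0.5) < 6 * se))
  # linkage: neighbouring variants on a chromosome co-segregate far more
  # often than variants on different chromosomes
  i <- which(muts$chrom == "1")[1:2]
  j <- c(which(muts$chrom == "1")[1], which(muts$chrom == "2")[1])
  same_chr <- mean(carried[i[1], ] == carried[i[2], ])
  diff_chr <- mean(carried[j[1], ] == carried[j[2], ])
  expect_gt(same_chr, 0.9)
  expect_lt(abs(diff_chr - 0.5), 0.15)
})

test_that("a clean simulated pool is homozygous-causal with consistent reads", {
  set.seed(61)
  cfg <- small_cfg(seed = 61)
  sim <- simulate_cross(cfg)
  causal_idx <- which(sim$muts$causal)
  expect_true(all(sim$genotypes[causal_idx, ] == 2L))
  expect_equal(ncol(sim$genotypes), cfg$pool_size)

  # emitted pooled reads are consistent with the recorded genotypes:
  # no site with pool dosage 0 is emitted, and with zero sequencing error
  # a fully homozygous site reads NAF exactly 1
  dosage <- rowSums(sim$genotypes)
  emitted <- paste(sim$pooled$chrom, sim$pooled$pos)
  all_sites <- paste(sim$muts$chrom, sim$muts$pos)
  expect_false(any(emitted %in% all_sites[dosage == 0]))
  causal_site <- match(paste(sim$causal$chrom, sim$causal$pos), emitted)
  expect_equal(sim$pooled$naf[causal_site], 1)
  full <- match(all_sites[dosage == 2 * cfg$pool_size], emitted)
  expect_true(all(sim$pooled$naf[full[!is.na(full)]] == 1))

  # pooled NAF tracks dosage on average
  obs <- sim$pooled$naf
  exp_naf <- dosage[match(emitted, all_sites)] / (2 * cfg$pool_size)
  expect_lt(abs(mean(obs - exp_naf)), 0.03)
})

test_that("simulator output parses back through the VCF reader cleanly", {
  set.seed(63)
  sim <- simulate_cross(small_cfg(seed = 63))
  dir <- tempfile()
  write_sim_output(sim, dir)
  expect_no_warning(v <- read_vcf(file.path(dir, "pooled.vcf")))
  expect_equal(nrow(v), nrow(sim$pooled))
  expect_equal(v$naf, sim$pooled$naf, tolerance = 1e-6)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_gt(n_intervals(read_bed(file.path(dir, "exons.bed"))), 0)
  layout <- read_genome_tsv(file.path(dir, "genome.tsv"))
  expect_equal(layout$chrom, sim$cfg$layout$chrom)
})

test_that("the screen's affected fraction matches 12.5% x penetrance", {
  set.seed(67)
  aff <- simulate_screen(small_cfg(), 20000)
  p <- 0.125
  expect_lt(abs(mean(aff) - p), 3 * sqrt(p * (1 - p) / length(aff)))

  aff6 <- simulate_screen(small_cfg(penetrance = 0.6), 20000)
  expect_lt(abs(mean(aff6) - 0.075), 3 * sqrt(0.075 * 0.925 / length(aff6)))
})

test_that("spiking a heterozygous outlier dilutes the causal site to (2N-1)/2N", {
  set.seed(71)
  cfg <- small_cfg(coverage = 400, seed = 71)  # deep pool: tight NAF
  sim <- simulate_cross(cfg)
  spiked <- spike_outlier(sim, "het")
  causal_idx <- which(spiked$muts$causal)
  expect_equal(sum(spiked$genotypes[causal_idx, ] == 2L), cfg$pool_size - 1L)
  expect_equal(sum(spiked$genotypes[causal_idx, ] == 1L), 1L)
  site <- which(spiked$pooled$chrom == spiked$causal$chrom &
                  spiked$pooled$pos == spiked$causal$pos)
  want <- (2 * cfg$pool_size - 1) / (2 * cfg$pool_size)  # 7/8
  expect_lt(abs(spiked$pooled$naf[site] - want), 0.05)

  one <- simulate_cross(small_cfg(pool_size = 1, seed = 72))
  expect_error(spike_outlier(one), "pool_size >= 2")
})
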