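# fixtures are built in code at test time

toy_layout <- function() {
  genome_layout(c("1", "2", "3", "X"), c(50e6, 40e6, 30e6, 20e6))
}

# write a small VCF by hand, independent of write_vcf()
write_toy_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                          contigs = c("1", "2", "3")) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=50000000>", contigs),
              '##INFO=<ID=DP,Number=1,Type=Integer,Description="d">',
              '##INFO=<ID=AD,Number=R,Type=Integer,Description="a">',
              '##INFO=<ID=DP4,Number=4,Type=Integer,Description="d4">',
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  writeLines(c(header, records), path)
  path
}

random_variants <- function(n, chroms = c("1", "2", "3"), max_pos = 50e6,
                            depth_range = c(5, 40)) {
  depth <- sample(depth_range[1]:depth_range[2], n, replace = TRUE)
  variant_table(chrom = sample(chroms, n, replace = TRUE),
                pos = sample.int(max_pos, n, replace = TRUE),
                ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                qual = stats::runif(n, 30, 90), depth = depth,
                alt_depth = stats::rbinom(n, depth, stats::runif(n)))
}

# filter fixture constructed to trip each of the seven rules exactly once,
# plus 2 survivors (including the boundary values Q30 and 5x)
trip_fixture <- function() {
  variant_table(
    chrom = c("1", "1", "1", "1", "1", "1", "X", "1", "2"),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L, 900L),
    ref = rep("A", 9), alt = rep("T", 9),
    alts = c("T", "T", "T", "T", "T", "T,G", "T", "T", "T"),
    qual = c(50, 50, 50, 29.9, 50, 50, 50, 30, 60),
    depth = c(10L, 10L, 10L, 10L, 4L, 10L, 10L, 5L, 12L),
    alt_depth = c(10L, 10L, 10L, 10L, 4L, 10L, 10L, 5L, 6L))
}

# naive per-window rescan: the oracle for score_windows
naive_score_windows <- function(variants, windows, cfg) {
  for (i in seq_len(nrow(windows))) {
    inside <- variants$chrom == windows$chrom[i] &
      variants$pos - 1 >= windows$start[i] &
      variants$pos - 1 < windows$end[i]
    n <- sum(inside)
    windows$n_snps[i] <- n
    if (n == 0) {
      windows$hom_count[i] <- NA_integer_
      windows$hom_pct[i] <- NA_real_
      windows$avg_naf[i] <- NA_real_
    } else {
      hom <- sum(variants$naf[inside] >= cfg$hom_naf_threshold)
      windows$hom_count[i] <- hom
      windows$hom_pct[i] <- 100 * hom / n
      windows$avg_naf[i] <- mean(variants$naf[inside])
    }
  }
  windows
}

# naive linear-scan membership: the oracle for in_intervals
naive_membership <- function(df, chrom, pos0) {
  vapply(seq_along(chrom), function(i) {
    any(df$chrom == chrom[i] & df$start <= pos0[i] & df$end > pos0[i])
  }, logical(1))
}

# naive per-position annotation by explicit distance computation
naive_annotate_one <- function(chrom, pos, exons, splice_margin = 10) {
  pos0 <- pos - 1
  e <- exons[exons$chrom == chrom, , drop = FALSE]
  if (!nrow(e)) return("intergenic")
  if (any(pos0 >= e$start & pos0 < e$end)) return("unknown")
  dist <- rep(Inf, nrow(e))
  left <- pos0 < e$start
  dist[left] <- e$start[left] - pos0
  right <- pos0 >= e$end
  dist[right] <- pos0 - e$end[right] + 1
  if (min(dist) <= splice_margin) return("splicing")
  for (g in unique(e$name)) {
    gb <- e[e$name == g, ]
    if (pos0 >= min(gb$start) && pos0 < max(gb$end)) return("intronic")
  }
  "intergenic"
}
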