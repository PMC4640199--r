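test_that("NAF is computed from DP and AD, with DP4 fallback", {
  path <- write_toy_vcf(c(
    "1\t100\t.\tA\tT\t60\t.\tDP=10;AD=0,10",
    "1\t200\t.\tC\tG\t45\t.\tDP=12;AD=3,9",
    "2\t300\t.\tG\tA\t50\t.\tDP=20;DP4=5,5,6,4"))
  v <- read_vcf(path)
  expect_equal(nrow(v), 3L)
  expect_equal(v$naf, c(1.0, 0.75, 0.5))
  expect_equal(v$depth, c(10L, 12L, 20L))
  expect_equal(v$alt_depth, c(10L, 9L, 10L))
})

test_that("records lacking depth get depth 0 (warning) or error under strict", {
  path <- write_toy_vcf("1\t100\t.\tA\tT\t60\t.\tNS=1")
  expect_warning(v <- read_vcf(path), "depth")
  expect_equal(v$depth, 0L)
  expect_true(is.na(v$naf))
  expect_error(read_vcf(path, strict = TRUE), "depth")
})

test_that("malformed VCFs fail with a line number", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1\t100\t.\tA\tT\t60\t.\tDP=10;AD=0,10",
               "1\t200\t.\tA"), bad)
  expect_error(read_vcf(bad), "line 4")
  noheader <- tempfile(fileext = ".vcf")
  writeLines(c("1\t100\t.\tA\tT\t60\t.\tDP=10"), noheader)
  expect_error(read_vcf(noheader), "line 1")
})

test_that("VCF round-trips: read(write(v)) preserves all variant fields", {
  set.seed(7)
  v <- random_variants(10)
  v$qual <- round(v$qual, 1)  # the writer prints 6 significant digits
  v$gene[1:3] <- c("Clcn1", "Abca12", "Pcsk5")
  v$category[1:3] <- c("stopgain", "splicing", "exonic_nonsynonymous")
  v$aa_change[1] <- "p.R100*"
  v$in_known_db[4] <- TRUE
  v$in_repeat[5] <- TRUE
  v$alts[6] <- paste0(v$alt[6], ",G")
  v$multiallelic[6] <- TRUE
  layout <- toy_layout()
  v <- v[order(match(v$chrom, layout$chrom), v$pos), ]
  path <- tempfile(fileext = ".vcf")
  write_vcf(v, layout, path)
  v2 <- read_vcf(path)
  rownames(v) <- NULL
  expect_equal(as.data.frame(v2), as.data.frame(v), tolerance = 1e-12)

  # and the written body is byte-stable under a second round trip
  path2 <- tempfile(fileext = ".vcf")
  write_vcf(v2, layout, path2)
  body <- function(p) grep("^#", readLines(p), invert = TRUE, value = TRUE)
  expect_identical(body(path2), body(path))
})

test_that("writing rejects unsorted input and emits header-only for empty", {
  layout <- toy_layout()
  v <- variant_table(chrom = c("1", "1"), pos = c(200L, 100L),
                     ref = c("A", "C"), alt = c("T", "G"),
                     qual = c(50, 50), depth = c(10L, 10L),
                     alt_depth = c(5L, 5L))
  expect_error(write_vcf(v, layout, tempfile()), "sorted")

  path <- tempfile(fileext = ".vcf")
  write_vcf(variant_table(), layout, path)
  lines <- readLines(path)
  expect_true(all(grepl("^#", lines)))
  expect_equal(nrow(read_vcf(path)), 0L)
})

test_that("naf is invariant under scaling depth and alt_depth together", {
  for (k in c(2L, 5L, 17L)) {
    v1 <- variant_table(chrom = "1", pos = 10L, ref = "A", alt = "T",
                        qual = 50, depth = 12L, alt_depth = 9L)
    vk <- variant_table(chrom = "1", pos = 10L, ref = "A", alt = "T",
                        qual = 50, depth = 12L * k, alt_depth = 9L * k)
    expect_identical(vk$naf, v1$naf)
  }
})

test_that("BED reading merges overlaps and validates coordinates", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t300"), path)
  iset <- read_bed(path)
  expect_equal(n_intervals(iset), 1L)
  expect_equal(iset$intervals$chr1, data.frame(start = 100, end = 300))

  empty <- tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  e <- read_bed(empty)
  expect_equal(n_intervals(e), 0L)
  expect_false(any(in_intervals(e, "chr1", c(0, 150))))

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t500\t400"), bad)
  expect_error(read_bed(bad), "line 2")
})

test_that("interval membership agrees with a naive linear scan", {
  set.seed(11)
  n <- 1000
  df <- data.frame(chrom = sample(c("1", "2", "3"), n, replace = TRUE),
                   start = sample.int(1e6, n, replace = TRUE))
  df$end <- df$start + sample.int(5000, n, replace = TRUE)
  iset <- interval_set(df$chrom, df$start, df$end)
  probes_chrom <- sample(c("1", "2", "3", "4"), 10000, replace = TRUE)
  probes_pos <- sample.int(1.1e6, 10000, replace = TRUE)
  expect_identical(in_intervals(iset, probes_chrom, probes_pos),
                   naive_membership(df, probes_chrom, probes_pos))
})

test_that("interval annotation honours the 10 bp splice margin exactly", {
  # one exon, 0-based [1000, 1200) = 1-based 1001..1200
  exons <- data.frame(chrom = "1", start = 1000, end = 1200, name = "gA")
  cat_at <- function(pos) {
    v <- variant_table(chrom = "1", pos = pos, ref = "A", alt = "T",
                       qual = 50, depth = 10L, alt_depth = 10L)
    annotate_by_intervals(v, exons)$category
  }
  expect_equal(cat_at(1001L), "unknown")     # exon start: exonic
  expect_equal(cat_at(1200L), "unknown")     # exon end: exonic
  expect_equal(cat_at(1210L), "splicing")    # exon end + 10: splice site
  expect_equal(cat_at(1211L), "intergenic")  # exon end + 11: outside
  expect_equal(cat_at(991L), "splicing")     # exon start - 10
  expect_equal(cat_at(990L), "intergenic")   # exon start - 11
})

test_that("interval annotation agrees with naive distance computation", {
  set.seed(23)
  exons <- data.frame(
    chrom = sample(c("1", "2"), 40, replace = TRUE),
    start = sort(sample.int(2e5, 40)))
  exons$end <- exons$start + sample(50:500, 40, replace = TRUE)
  exons$name <- paste0("g", rep(1:8, each = 5))
  pos <- sample.int(2.1e5, 500, replace = TRUE)
  chrom <- sample(c("1", "2"), 500, replace = TRUE)
  v <- variant_table(chrom = chrom, pos = pos, ref = "A", alt = "T",
                     qual = 50, depth = rep(10L, 500),
                     alt_depth = rep(10L, 500))
  got <- annotate_by_intervals(v, exons)$category
  want <- vapply(seq_along(pos), function(i) {
    naive_annotate_one(chrom[i], pos[i], exons)
  }, character(1))
  expect_identical(got, want)
})

test_that("pre-attached annotation wins over interval annotation", {
  exons <- data.frame(chrom = "1", start = 1000, end = 1200, name = "gA")
  v <- variant_table(chrom = "1", pos = 1100L, ref = "A", alt = "T",
                     qual = 50, depth = 10L, alt_depth = 10L,
                     gene = "gB", category = "stopgain")
  out <- annotate_by_intervals(v, exons)
  expect_equal(out$category, "stopgain")
  expect_equal(out$gene, "gB")
})

test_that("layout validation rejects bad inputs", {
  expect_error(genome_layout(c("1", "1"), c(10, 20)), "unique")
  expect_error(genome_layout("1", 0), "positive")
  expect_error(interval_set("1", 200, 100), "start >= end")
})
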