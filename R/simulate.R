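#' Simulator configuration
#'
#' Settings for the forward simulator of the breeding scheme: a G1 male
#' carrying one fully mutagenized haplotype per chromosome (ENU acts on G0
#' spermatogonia, so the G1 inherits a single mutagenized gamete), crossed
#' to wild-type females; G2 daughters backcrossed to the G1; G3 offspring
#' screened until `pool_size` affected (homozygous causal, penetrant) mice
#' are collected and sequenced as one un-barcoded pool.
#'
#' Defaults reflect the mapping study conditions: ~1.2 induced SNVs per Mb
#' (about 3000 genome-wide on the 19 x 130 Mb desk genome), a uniform
#' 0.5 cM/Mb Haldane recombination map, pools of 4 affected mice, mean
#' pooled depth 15x, full penetrance.
#'
#' @param layout A [genome_layout()] of autosomes (default [desk_layout()]).
#' @param mutation_rate Induced variants per Mb (default 1.2).
#' @param recomb_rate Recombination rate in cM per Mb (default 0.5).
#' @param pool_size Number of affected mice pooled (default 4).
#' @param coverage Mean pooled read depth per site (Poisson, default 15).
#' @param penetrance P(affected | homozygous causal), in (0, 1].
#' @param n_g2_dams Number of G2 dams contributing screened G3 offspring.
#' @param causal_choice `"random_exonic"` (a random damaging exon-resident
#'   variant) or a fixed `c(chrom, pos)` position.
#' @param exon_fraction Fraction of variants assigned exon-resident
#'   categories (default 0.05).
#' @param seq_error Per-read base error probability (default 0.001).
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(layout = desk_layout(), mutation_rate = 1.2,
                       recomb_rate = 0.5, pool_size = 4, coverage = 15,
                       penetrance = 1, n_g2_dams = 4,
                       causal_choice = "random_exonic",
                       exon_fraction = 0.05, seq_error = 0.001,
                       seed = NULL) {
  stopifnot(inherits(layout, "genome_layout"), mutation_rate > 0,
            recomb_rate >= 0, pool_size >= 1, coverage > 0,
            penetrance > 0, penetrance <= 1, n_g2_dams >= 1,
            exon_fraction >= 0, exon_fraction < 1,
            seq_error >= 0, seq_error < 0.5)
  structure(list(layout = layout, mutation_rate = mutation_rate,
                 recomb_rate = recomb_rate, pool_size = pool_size,
                 coverage = coverage, penetrance = penetrance,
                 n_g2_dams = n_g2_dams, causal_choice = causal_choice,
                 exon_fraction = exon_fraction, seq_error = seq_error,
                 seed = seed),
            class = "sim_config")
}

# category mix: within the exon-resident fraction, mostly missense with a
# minority of synonymous, nonsense and splice-site changes (ENU-typical);
# the non-exonic remainder splits between intronic and intergenic.
exon_category_weights <- c(exonic_nonsynonymous = 0.55,
                           exonic_synonymous = 0.25,
                           stopgain = 0.05, splicing = 0.15)
nonexon_category_weights <- c(intronic = 0.4, intergenic = 0.6)

#' Draw the G1 founder's induced mutations
#'
#' The number of variants is Poisson with mean `mutation_rate` x genome Mb
#' (about 3000 for the defaults); positions are uniform within each
#' chromosome, each variant gets a random substitution, a synthetic gene
#' label, and a functional category drawn from an ENU-typical mix with
#' `exon_fraction` exon-resident. One damaging exon-resident variant is
#' designated causal (`causal_choice = "random_exonic"`), or a fixed
#' position is inserted as a stopgain causal variant.
#'
#' @param cfg A [sim_config()].
#' @return A data frame with columns chrom, pos, ref, alt, gene, category,
#'   aa_change, causal.
#' @export
draw_mutations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  auto <- autosomes(cfg$layout)
  genome_mb <- sum(auto$length) / 1e6
  n <- stats::rpois(1, cfg$mutation_rate * genome_mb)
  chrom <- sample(auto$chrom, n, replace = TRUE,
                  prob = auto$length / sum(auto$length))
  pos <- vapply(match(chrom, auto$chrom), function(i) {
    1L + as.integer(floor(stats::runif(1) * auto$length[i]))
  }, integer(1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  weights <- c(exon_category_weights * cfg$exon_fraction,
               nonexon_category_weights * (1 - cfg$exon_fraction))
  category <- sample(names(weights), n, replace = TRUE, prob = weights)
  muts <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     gene = sprintf("gene%05d", seq_len(max(n, 1))[seq_len(n)]),
                     category = category,
                     aa_change = NA_character_, causal = FALSE,
                     stringsAsFactors = FALSE)
  coding <- muts$category %in% c("exonic_nonsynonymous", "exonic_synonymous",
                                 "stopgain")
  muts$aa_change[coding] <- sprintf("p.X%dY", 1L + (muts$pos[coding] %% 500L))

  if (identical(cfg$causal_choice, "random_exonic")) {
    eligible <- which(muts$category %in% DAMAGING_CATEGORIES)
    if (!length(eligible)) {
      # a single redraw, then give up: the configuration is degenerate
      return(draw_mutations_retry(cfg))
    }
    muts$causal[sample_one(eligible)] <- TRUE
  } else {
    fixed <- cfg$causal_choice
    muts <- rbind(muts, data.frame(
      chrom = as.character(fixed[1]), pos = as.integer(fixed[2]),
      ref = "A", alt = "T", gene = "gene_causal", category = "stopgain",
      aa_change = "p.R100*", causal = TRUE, stringsAsFactors = FALSE))
  }
  ord <- genome_order(muts, cfg$layout)
  muts <- muts[ord, , drop = FALSE]
  rownames(muts) <- NULL
  muts
}

draw_mutations_retry <- function(cfg) {
  muts <- draw_mutations_once_no_causal(cfg)
  eligible <- which(muts$category %in% DAMAGING_CATEGORIES)
  if (!length(eligible)) {
    stop("no damaging exon-resident variant drawn after a redraw; ",
         "increase exon_fraction or mutation_rate, or fix the causal position")
  }
  muts$causal[sample_one(eligible)] <- TRUE
  ord <- genome_order(muts, cfg$layout)
  muts <- muts[ord, , drop = FALSE]
  rownames(muts) <- NULL
  muts
}

draw_mutations_once_no_causal <- function(cfg) {
  cfg2 <- cfg
  cfg2$causal_choice <- c(autosomes(cfg$layout)$chrom[1], 1)
  muts <- draw_mutations(cfg2)
  muts <- muts[!muts$causal, , drop = FALSE]
  muts
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Simulate one meiosis
#'
#' Produces a recombinant gamete from two parental haplotypes under a
#' Haldane (no-interference) model: per chromosome the crossover count is
#' Poisson with mean `length_Mb * recomb_rate / 100` Morgans, breakpoints
#' are uniform, the starting homolog is a fair coin, and the gamete
#' alternates source homolog at each breakpoint. Haplotypes are logical
#' carrier vectors aligned to the rows of `muts`.
#'
#' @param hap_a,hap_b Logical vectors over the rows of `muts`.
#' @param muts Mutation table from [draw_mutations()].
#' @param cfg A [sim_config()].
#' @return A logical carrier vector for the gamete.
#' @export
meiosis <- function(hap_a, hap_b, muts, cfg) {
  stopifnot(length(hap_a) == nrow(muts), length(hap_b) == nrow(muts))
  out <- logical(nrow(muts))
  auto <- autosomes(cfg$layout)
  idx_by_chrom <- split(seq_len(nrow(muts)), muts$chrom)
  for (i in seq_len(nrow(auto))) {
    ch <- auto$chrom[i]
    idx <- idx_by_chrom[[ch]]
    morgans <- auto$length[i] / 1e6 * cfg$recomb_rate / 100
    k <- stats::rpois(1, morgans)
    from_a <- stats::runif(1) < 0.5
    if (is.null(idx)) next
    if (k == 0L) {
      out[idx] <- if (from_a) hap_a[idx] else hap_b[idx]
    } else {
      breaks <- sort(stats::runif(k, 0, auto$length[i]))
      seg <- findInterval(muts$pos[idx] - 1, breaks)
      use_a <- xor(seg %% 2 == 1, from_a)
      out[idx] <- ifelse(use_a, hap_a[idx], hap_b[idx])
    }
  }
  out
}

#' Simulate the full breeding scheme and pooled sequencing
#'
#' Builds the G1 male (one fully mutant haplotype, one wild-type),
#' generates `n_g2_dams` G2 daughters (a G1 gamete paired with a wild-type
#' gamete), then draws G3 backcross offspring (G1 gamete x dam gamete)
#' until `pool_size` are affected — homozygous for the causal variant and
#' penetrant. Dam sets with no causal carrier cannot produce affected
#' offspring and are redrawn (counted in the output). The affected mice
#' are sequenced as one pool: per variant, total depth is Poisson with
#' mean `coverage`, alternate reads are Binomial(depth, dosage / 2N), and
#' each read flips allele with probability `seq_error`. Sites with no
#' alternate read in the pool are not emitted (a pooled caller would not
#' report them).
#'
#' @param cfg A [sim_config()]. `cfg$seed`, when set, seeds the simulation.
#' @return An object of class `enu_sim`: a list with `muts` (truth mutation
#'   table), `causal` (its causal row), `genotypes` (variants x pool
#'   dosage matrix), `dam_ids`, `pooled` (the emitted [variant_table()]),
#'   `n_screened`, `n_dam_redraws`, and `cfg`.
#' @export
simulate_cross <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  muts <- draw_mutations(cfg)
  n_var <- nrow(muts)
  causal_idx <- which(muts$causal)

  hap_mut <- rep(TRUE, n_var)   # the mutagenized G1 haplotype
  hap_wt <- rep(FALSE, n_var)

  n_dam_redraws <- 0L
  repeat {
    dam_haps <- lapply(seq_len(cfg$n_g2_dams), function(i) {
      meiosis(hap_mut, hap_wt, muts, cfg)
    })
    if (any(vapply(dam_haps, function(h) h[causal_idx], logical(1)))) break
    n_dam_redraws <- n_dam_redraws + 1L
    if (n_dam_redraws > 1000L) stop("no carrier dam after 1000 redraws")
  }

  genotypes <- matrix(0L, nrow = n_var, ncol = cfg$pool_size)
  dam_ids <- integer(cfg$pool_size)
  n_screened <- 0L
  found <- 0L
  while (found < cfg$pool_size) {
    n_screened <- n_screened + 1L
    if (n_screened > 100000L) stop("screening cap reached without filling the pool")
    dam <- sample.int(cfg$n_g2_dams, 1L)
    g_sire <- meiosis(hap_mut, hap_wt, muts, cfg)
    g_dam <- meiosis(dam_haps[[dam]], hap_wt, muts, cfg)
    dosage <- g_sire + g_dam
    affected <- dosage[causal_idx] == 2L && stats::runif(1) < cfg$penetrance
    if (affected) {
      found <- found + 1L
      genotypes[, found] <- dosage
      dam_ids[found] <- dam
    }
  }

  sim <- structure(list(muts = muts, causal = muts[causal_idx, , drop = FALSE],
                        genotypes = genotypes, dam_ids = dam_ids,
                        pooled = NULL, n_screened = n_screened,
                        n_dam_redraws = n_dam_redraws,
                        dam_haps = dam_haps, cfg = cfg),
                   class = "enu_sim")
  sim$pooled <- pool_reads(sim)
  sim
}

# pooled read sampling from the recorded per-mouse genotypes
pool_reads <- function(sim) {
  cfg <- sim$cfg
  muts <- sim$muts
  n_var <- nrow(muts)
  dosage_total <- rowSums(sim$genotypes)
  depth <- stats::rpois(n_var, cfg$coverage)
  alt_true <- stats::rbinom(n_var, depth, dosage_total / (2 * cfg$pool_size))
  if (cfg$seq_error > 0) {
    alt_obs <- stats::rbinom(n_var, alt_true, 1 - cfg$seq_error) +
      stats::rbinom(n_var, depth - alt_true, cfg$seq_error)
  } else {
    alt_obs <- alt_true
  }
  emit <- alt_obs >= 1L & depth > 0L
  variant_table(chrom = muts$chrom[emit], pos = muts$pos[emit],
                ref = muts$ref[emit], alt = muts$alt[emit],
                qual = 60, depth = depth[emit], alt_depth = alt_obs[emit],
                gene = muts$gene[emit], category = muts$category[emit],
                aa_change = muts$aa_change[emit])
}

#' @export
print.enu_sim <- function(x, ...) {
  cat("Simulated G1 x G2 backcross pool\n")
  cat("  induced variants :", nrow(x$muts), "\n")
  cat("  causal           :", x$causal$gene, x$causal$category, "at",
      paste0(x$causal$chrom, ":", x$causal$pos), "\n")
  cat("  pool             :", x$cfg$pool_size, "affected of",
      x$n_screened, "screened G3 mice\n")
  cat("  emitted sites    :", nrow(x$pooled), "\n")
  invisible(x)
}

#' Spike a non-homozygous outlier into a simulated pool
#'
#' Replaces one pooled mouse with a mouse that is heterozygous (or
#' wild-type) at the causal locus — a heterozygous phenocopy, a mistaken
#' ascertainment, or a sample-handling error — and regenerates the pooled
#' reads. With a heterozygous outlier the expected causal-site NAF drops
#' from 1 to (2N - 1) / 2N, which can defeat the strict homozygosity
#' criterion while leaving the NAF criterion informative.
#'
#' @param sim An `enu_sim` from [simulate_cross()] with `pool_size >= 2`.
#' @param outlier `"het"` or `"wt"`: required causal genotype of the
#'   replacement mouse.
#' @return The modified `enu_sim` (truth and pooled reads updated,
#'   `spiked_mouse` records the replaced column).
#' @export
spike_outlier <- function(sim, outlier = c("het", "wt")) {
  stopifnot(inherits(sim, "enu_sim"))
  outlier <- match.arg(outlier)
  cfg <- sim$cfg
  if (cfg$pool_size < 2) stop("spiking requires pool_size >= 2")
  target <- if (outlier == "het") 1L else 0L
  causal_idx <- which(sim$muts$causal)
  hap_mut <- rep(TRUE, nrow(sim$muts))
  hap_wt <- rep(FALSE, nrow(sim$muts))
  repeat {
    dam <- sample.int(cfg$n_g2_dams, 1L)
    g_sire <- meiosis(hap_mut, hap_wt, sim$muts, cfg)
    g_dam <- meiosis(sim$dam_haps[[dam]], hap_wt, sim$muts, cfg)
    dosage <- g_sire + g_dam
    if (dosage[causal_idx] == target) break
  }
  replace <- sample.int(cfg$pool_size, 1L)
  sim$genotypes[, replace] <- dosage
  sim$dam_ids[replace] <- dam
  sim$spiked_mouse <- replace
  sim$pooled <- pool_reads(sim)
  sim
}

#' Simulate a G3 screen at the causal locus
#'
#' Draws `n_offspring` G3 mice through the pedigree (fresh dam sets of
#' `n_g2_dams` G2 daughters, offspring assigned to dams round-robin) and
#' records affected status. Transmission is simulated at the causal locus
#' only — marginally at one position, a meiosis hands down either parental
#' allele with probability 1/2 — which makes screens of tens of thousands
#' of mice instant. Unlike [simulate_cross()], dam sets without a carrier
#' are retained, so the affected fraction is the marginal one (expected
#' 12.5% x penetrance).
#'
#' @param cfg A [sim_config()].
#' @param n_offspring Number of G3 mice to screen.
#' @return Logical vector of affected status, length `n_offspring`.
#' @export
simulate_screen <- function(cfg, n_offspring) {
  stopifnot(inherits(cfg, "sim_config"))
  per_family <- cfg$n_g2_dams * 8L  # litters of 8 per dam, round numbers
  n_fam <- ceiling(n_offspring / per_family)
  affected <- logical(0)
  for (f in seq_len(n_fam)) {
    dam_carrier <- stats::rbinom(cfg$n_g2_dams, 1, 0.5) == 1L
    dams <- rep_len(seq_len(cfg$n_g2_dams), per_family)
    sire_allele <- stats::rbinom(per_family, 1, 0.5) == 1L
    dam_allele <- dam_carrier[dams] & stats::rbinom(per_family, 1, 0.5) == 1L
    hom <- sire_allele & dam_allele
    affected <- c(affected,
                  hom & stats::runif(per_family) < cfg$penetrance)
  }
  affected[seq_len(n_offspring)]
}

#' Write simulator output to a directory
#'
#' Writes `pooled.vcf` (the emitted pooled call set), `truth.json` (causal
#' variant, per-mouse genotypes at every variant, dam identities, screen
#' counts), `genome.tsv` (the layout) and `exons.bed` (a synthetic exon
#' model: one exon around each exon-resident variant, labelled with its
#' gene).
#'
#' @param sim An `enu_sim` from [simulate_cross()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "enu_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$pooled, sim$cfg$layout, file.path(dir, "pooled.vcf"))
  write_genome_tsv(sim$cfg$layout, file.path(dir, "genome.tsv"))
  ex <- sim$muts[sim$muts$category %in% EXON_RESIDENT_CATEGORIES, ,
                 drop = FALSE]
  exon_start <- pmax(0, ex$pos - 51)
  writeLines(sprintf("%s\t%d\t%d\t%s", ex$chrom, as.integer(exon_start),
                     as.integer(ex$pos + 100), ex$gene),
             file.path(dir, "exons.bed"))
  truth <- list(causal = as.list(sim$causal[1, c("chrom", "pos", "gene",
                                                 "category")]),
                n_variants = nrow(sim$muts),
                n_screened = sim$n_screened,
                n_dam_redraws = sim$n_dam_redraws,
                dam_ids = sim$dam_ids,
                variants = sim$muts[, c("chrom", "pos", "gene", "category")],
                genotypes = unname(split(t(sim$genotypes),
                                         seq_len(ncol(sim$genotypes)))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
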