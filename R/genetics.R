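#' Closed-form genetics of the G1 x G2 backcross scheme
#'
#' In the breeding scheme, a mutagenized founder's son (G1) is crossed to
#' wild-type females and then backcrossed to his G2 daughters; recessive
#' phenotypes appear in the G3. The G1 male is heterozygous for every
#' induced variant, so a given G2 daughter inherits a specific variant
#' with probability `p_g2_carrier` (1/2), and a G3 offspring of a carrier
#' dam is homozygous with probability `p_hom_given_carrier` (1/4: the
#' het x het backcross).
#'
#' @param p_g2_carrier Probability that a G2 dam carries a given G1
#'   variant (default 1/2).
#' @param p_hom_given_carrier Probability that a backcross offspring of a
#'   carrier dam is homozygous (default 1/4).
#' @param penetrance Probability that a homozygous-mutant mouse expresses
#'   the phenotype.
#' @param pool_size Number of affected mice pooled for sequencing.
#' @return An object of class `cross_model`.
#' @export
cross_model <- function(p_g2_carrier = 0.5, p_hom_given_carrier = 0.25,
                        penetrance = 1, pool_size = 4) {
  p <- c(p_g2_carrier, p_hom_given_carrier, penetrance)
  stopifnot(all(p >= 0 & p <= 1), pool_size >= 1)
  structure(list(p_g2_carrier = p_g2_carrier,
                 p_hom_given_carrier = p_hom_given_carrier,
                 penetrance = penetrance, pool_size = pool_size),
            class = "cross_model")
}

#' @export
print.cross_model <- function(x, ...) {
  cat("G1 x G2 backcross model\n")
  cat("  P(G2 dam carries a variant)      :", x$p_g2_carrier, "\n")
  cat("  P(offspring hom | carrier dam)   :", x$p_hom_given_carrier, "\n")
  cat("  penetrance                       :", x$penetrance, "\n")
  cat("  pool size                        :", x$pool_size, "\n")
  cat("  P(unlinked locus hom, one mouse) :", p_homozygous_unlinked(x), "\n")
  cat("  P(spurious hom region, pool)     :",
      p_spurious_region(x, x$pool_size), "\n")
  cat("  expected affected G3 fraction    :", expected_affected_fraction(x),
      "\n")
  invisible(x)
}

#' Per-mouse probability of spurious homozygosity at an unlinked locus
#'
#' The probability that a single G3 mouse is homozygous for a G1-derived
#' variant at a locus unlinked to the causal mutation:
#' `p_g2_carrier * p_hom_given_carrier` (0.125 for the default scheme).
#' All default probabilities are dyadic, so the arithmetic is exact in
#' floating point.
#'
#' @param model A [cross_model()].
#' @return A probability.
#' @export
p_homozygous_unlinked <- function(model = cross_model()) {
  stopifnot(inherits(model, "cross_model"))
  model$p_g2_carrier * model$p_hom_given_carrier
}

#' Probability that a whole pool is spuriously homozygous
#'
#' The probability that every one of `n` pooled mice is homozygous for the
#' G1 allele at an unlinked locus — the rate at which the homozygosity
#' criterion flags a spurious region: `p_homozygous_unlinked ^ n`
#' (0.125^4 = 2.44e-4, ~0.0002, for the default pool of 4).
#'
#' @param model A [cross_model()].
#' @param n Pool size (>= 1); defaults to the model's pool size.
#' @return A probability, strictly decreasing in `n`.
#' @export
p_spurious_region <- function(model = cross_model(), n = model$pool_size) {
  stopifnot(inherits(model, "cross_model"))
  if (n < 1) stop("pool size must be >= 1")
  p_homozygous_unlinked(model)^n
}

#' Expected fraction of affected G3 progeny
#'
#' For a monogenic recessive mutation, the expected fraction of G3 mice
#' expressing the phenotype:
#' `p_g2_carrier * p_hom_given_carrier * penetrance` (12.5% for a fully
#' penetrant mutation).
#'
#' @param model A [cross_model()].
#' @return A fraction.
#' @export
expected_affected_fraction <- function(model = cross_model()) {
  stopifnot(inherits(model, "cross_model"))
  p_homozygous_unlinked(model) * model$penetrance
}

#' Expected pooled NAF at causal and unlinked loci
#'
#' The expected non-reference allele fraction of a pooled sample of
#' affected (homozygous-mutant) G3 mice, computed by exact enumeration of
#' the transmission outcomes (dam carrier status, sire-transmitted allele,
#' dam-transmitted allele):
#'
#' * `causal`: all pooled chromosomes carry the variant, so 1.
#' * `unlinked`, conditioned on a carrier dam: the het x het backcross,
#'   mean dosage 1 of 2 chromosomes, so 0.5 — the "random" background
#'   expectation against which elevated regions are judged.
#' * `unlinked`, marginal over dam status: 0.375 with the default model
#'   (1/2 x 1/2 + 1/2 x 1/4), since non-carrier dams transmit nothing.
#'
#' @param model A [cross_model()].
#' @param locus `"causal"` or `"unlinked"`.
#' @param conditioning For unlinked loci: `"dam_carrier"` (condition on
#'   the dam carrying the variant) or `"marginal"`.
#' @return Expected pooled allele fraction.
#' @export
expected_pool_naf <- function(model = cross_model(),
                              locus = c("causal", "unlinked"),
                              conditioning = c("dam_carrier", "marginal")) {
  stopifnot(inherits(model, "cross_model"))
  locus <- match.arg(locus)
  conditioning <- match.arg(conditioning)
  if (locus == "causal") return(1)
  # enumerate (dam carrier, sire allele, dam allele) outcomes
  outcomes <- expand.grid(carrier = c(1, 0), sire = c(1, 0), dam = c(1, 0))
  p_carrier <- ifelse(outcomes$carrier == 1, model$p_g2_carrier,
                      1 - model$p_g2_carrier)
  p_sire <- 0.5  # G1 sire is heterozygous at every induced variant
  p_dam <- ifelse(outcomes$carrier == 1,
                  0.5 * outcomes$dam + 0.5 * (1 - outcomes$dam),
                  1 - outcomes$dam)  # non-carrier dam never transmits
  prob <- p_carrier * p_sire * p_dam
  if (conditioning == "dam_carrier") {
    keep <- outcomes$carrier == 1
    prob <- prob[keep] / sum(prob[keep])
    outcomes <- outcomes[keep, , drop = FALSE]
  } else {
    prob <- prob / sum(prob)
  }
  sum(prob * (outcomes$sire + outcomes$dam) / 2)
}

# ---- Monte-Carlo counterparts -------------------------------------------
# Single-locus transmission draws through the same pedigree structure; the
# full multi-locus simulator (simulate_cross) is the cross-module check.

#' Monte-Carlo draws of unlinked-locus homozygosity
#'
#' Simulates `n` independent G3 mice at a locus unlinked to the causal
#' mutation: the dam carries the variant with probability `p_g2_carrier`;
#' a carrier dam and the het sire each transmit with probability 1/2.
#'
#' @param n Number of simulated mice.
#' @param model A [cross_model()].
#' @return Logical vector: is the mouse homozygous for the G1 allele?
#' @export
mc_unlinked_hom <- function(n, model = cross_model()) {
  carrier <- stats::rbinom(n, 1, model$p_g2_carrier)
  dam_allele <- carrier * stats::rbinom(n, 1, 0.5)
  sire_allele <- stats::rbinom(n, 1, 0.5)
  dam_allele == 1 & sire_allele == 1
}

#' Monte-Carlo estimate of the spurious-region probability
#'
#' Simulates pools of `pool_size` mice (each mouse an independent pedigree
#' draw as in [mc_unlinked_hom()]) and reports the fraction of pools in
#' which every mouse is homozygous at the unlinked locus.
#'
#' @param n_pools Number of simulated pools.
#' @param model A [cross_model()].
#' @param pool_size Pool size; defaults to the model's.
#' @return Fraction of all-homozygous pools.
#' @export
mc_spurious_region <- function(n_pools, model = cross_model(),
                               pool_size = model$pool_size) {
  hom <- matrix(mc_unlinked_hom(n_pools * pool_size, model),
                nrow = n_pools)
  mean(rowSums(hom) == pool_size)
}

#' Monte-Carlo draws of affected status in the G3
#'
#' Simulates G3 mice at the causal locus (dam carrier, transmissions,
#' penetrance) and returns affected status.
#'
#' @param n Number of simulated mice.
#' @param model A [cross_model()].
#' @return Logical vector: is the mouse phenotypically affected?
#' @export
mc_affected <- function(n, model = cross_model()) {
  hom <- mc_unlinked_hom(n, model)  # causal transmission is the same draw
  hom & stats::runif(n) < model$penetrance
}

#' Monte-Carlo pooled NAF at an unlinked locus
#'
#' Simulates pools of affected mice and returns, per pool, the allele
#' fraction at an unlinked locus (mean dosage over `2 * pool_size`
#' chromosomes). Under `"dam_carrier"` every pooled mouse's dam carries
#' the unlinked variant; under `"marginal"` dams carry it with probability
#' `p_g2_carrier`.
#'
#' @param n_pools Number of simulated pools.
#' @param model A [cross_model()].
#' @param conditioning `"dam_carrier"` or `"marginal"`.
#' @return Numeric vector of per-pool allele fractions.
#' @export
mc_pool_naf <- function(n_pools, model = cross_model(),
                        conditioning = c("dam_carrier", "marginal")) {
  conditioning <- match.arg(conditioning)
  n <- n_pools * model$pool_size
  carrier <- if (conditioning == "dam_carrier") {
    rep(1L, n)
  } else {
    stats::rbinom(n, 1, model$p_g2_carrier)
  }
  dosage <- carrier * stats::rbinom(n, 1, 0.5) + stats::rbinom(n, 1, 0.5)
  rowSums(matrix(dosage, nrow = n_pools)) / (2 * model$pool_size)
}
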