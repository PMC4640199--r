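#' Pipeline configuration
#'
#' Bundles the stage configurations for [run_all()]: either a VCF of
#' pooled calls (plus optional masks) or a simulator configuration as
#' input, the filter and window settings, the mapping criterion with its
#' thresholds, and the candidate-extraction mode.
#'
#' The `"auto"` criterion encodes the two-step decision process of the
#' mapping strategy: call regions by homozygosity percentage first and,
#' only when that yields no region (as happens when the pool contains a
#' non-homozygous mouse), fall back to the average-NAF criterion.
#'
#' @param vcf Path to a pooled-sample VCF (ignored when `sim` is given).
#' @param sim Optional [sim_config()] (the pipeline simulates its own
#'   input) or a ready-made `enu_sim` object, e.g. one spiked with
#'   [spike_outlier()]; either way the truth is carried in the manifest.
#' @param layout A [genome_layout()] (defaults to the simulator's).
#' @param known,controls Optional known-variant tables ([read_known()]).
#' @param repeats Optional repeat-mask [interval_set()].
#' @param filter A [filter_config()].
#' @param window A [window_config()].
#' @param criterion `"auto"`, `"homozygosity"` or `"naf"`.
#' @param hom_threshold Strict threshold on window hom percentage
#'   (default 50: a qualifying window has a majority of homozygous
#'   markers, far above the unlinked expectation).
#' @param definitive_hom Peak hom percentage a called region must exceed
#'   to count as definitive homozygosity (default 80). Under `"auto"`,
#'   the NAF fallback fires when no region is definitive — a pool
#'   contaminated by a non-homozygous mouse leaves its linked markers
#'   near 7/8 dosage, which produces at best weak, non-definitive
#'   homozygosity windows.
#' @param naf_threshold Strict threshold on window average NAF
#'   (default 0.7).
#' @param naf_floor Candidate NAF floor for the NAF strategy.
#' @param out_dir Output directory; `NULL` disables file output.
#' @param seed Integer seed for the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, sim = NULL, layout = NULL,
                            known = NULL, controls = NULL, repeats = NULL,
                            filter = filter_config(),
                            window = window_config(),
                            criterion = c("auto", "homozygosity", "naf"),
                            hom_threshold = 50, definitive_hom = 80,
                            naf_threshold = 0.7,
                            naf_floor = 0.7, out_dir = NULL, seed = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(vcf) && is.null(sim)) {
    stop("pipeline needs either a VCF path or a simulator configuration")
  }
  if (is.null(layout) && !is.null(sim)) {
    layout <- if (inherits(sim, "enu_sim")) sim$cfg$layout else sim$layout
  }
  if (is.null(layout)) stop("a genome layout is required with VCF input")
  structure(list(vcf = vcf, sim = sim, layout = layout, known = known,
                 controls = controls, repeats = repeats, filter = filter,
                 window = window, criterion = criterion,
                 hom_threshold = hom_threshold,
                 definitive_hom = definitive_hom,
                 naf_threshold = naf_threshold, naf_floor = naf_floor,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full mapping pipeline
#'
#' Executes simulate (optional), filter, window scoring, region calling
#' and candidate extraction in order, and returns a run manifest. Under
#' `criterion = "auto"` the homozygosity criterion is tried first and the
#' NAF criterion is used when it produces no region of definitive
#' homozygosity (no region at all, or none whose peak window exceeds
#' `definitive_hom` percent homozygous); `criterion_used` in the manifest
#' records the outcome. Candidates use the matching zygosity
#' mode: `require_hom = TRUE` under homozygosity, the NAF floor otherwise.
#' Identical configuration and seed give identical variants, windows,
#' regions and candidates.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress stage messages (written to stderr).
#' @return Invisibly, a list with `manifest` plus the stage outputs
#'   (`variants`, `report`, `windows`, `regions`, `candidates`, and `sim`
#'   when simulated). When `cfg$out_dir` is set, writes filtered.vcf,
#'   windows.tsv, regions.bed, candidates.tsv, report.json and
#'   manifest.json there.
#' @export
run_all <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message("[enumapper] ", ...)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  sim <- NULL
  if (!is.null(cfg$sim)) {
    if (inherits(cfg$sim, "enu_sim")) {
      say("stage simulate: using supplied simulation")
      sim <- cfg$sim
    } else {
      say("stage simulate")
      simcfg <- cfg$sim
      simcfg$seed <- NULL  # the pipeline seed already governs the stream
      sim <- simulate_cross(simcfg)
    }
    variants <- sim$pooled
  } else {
    say("stage read: ", cfg$vcf)
    variants <- read_vcf(cfg$vcf)
  }

  say("stage filter: ", nrow(variants), " variants in")
  fl <- filter_variants(variants, known = cfg$known,
                        controls = cfg$controls, repeats = cfg$repeats,
                        layout = cfg$layout, cfg = cfg$filter)
  say("stage filter: ", fl$report$passing_count, " passing")

  say("stage map")
  windows <- score_windows(fl$variants,
                           make_windows(cfg$layout, cfg$window),
                           cfg$window)
  criterion_used <- cfg$criterion
  if (cfg$criterion %in% c("auto", "homozygosity")) {
    regions <- find_regions(windows, "homozygosity", cfg$hom_threshold,
                            cfg$window, variants = fl$variants)
    criterion_used <- "homozygosity"
    definitive <- nrow(regions) > 0L &&
      max(regions$peak_value) > cfg$definitive_hom
    if (cfg$criterion == "auto" && !definitive) {
      say("no region of definitive homozygosity; ",
          "falling back to the NAF criterion")
      regions <- find_regions(windows, "naf", cfg$naf_threshold,
                              cfg$window, variants = fl$variants)
      criterion_used <- "naf"
    }
  } else {
    regions <- find_regions(windows, "naf", cfg$naf_threshold, cfg$window,
                            variants = fl$variants)
    criterion_used <- "naf"
  }
  say("stage map: ", nrow(regions), " region(s) by ", criterion_used)

  say("stage candidates")
  candidates <- candidate_mutations(
    fl$variants, regions, naf_floor = cfg$naf_floor,
    require_hom = criterion_used == "homozygosity",
    hom_naf_threshold = cfg$window$hom_naf_threshold)
  say("stage candidates: ", nrow(candidates))

  manifest <- list(
    tool = "enumapper",
    version = as.character(utils::packageVersion("enumapper")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    input = if (is.null(cfg$sim)) cfg$vcf else "simulated",
    thresholds = list(criterion = cfg$criterion,
                      hom_threshold = cfg$hom_threshold,
                      definitive_hom = cfg$definitive_hom,
                      naf_threshold = cfg$naf_threshold,
                      naf_floor = cfg$naf_floor,
                      window_size = cfg$window$size,
                      window_step = cfg$window$step,
                      hom_naf_threshold = cfg$window$hom_naf_threshold,
                      min_snps = cfg$window$min_snps),
    criterion_used = criterion_used,
    counts = c(unclass(fl$report),
               list(n_regions = nrow(regions),
                    n_candidates = nrow(candidates))),
    regions = regions[, c("chrom", "start", "end", "criterion",
                          "n_windows", "n_snps", "peak_value")],
    candidates = candidates[, c("gene", "naf", "chrom", "pos", "ref",
                                "alt", "category", "rank")])
  if (!is.null(sim)) {
    manifest$truth <- list(causal = as.list(sim$causal[1, c("chrom", "pos",
                                                            "gene",
                                                            "category")]),
                           n_variants = nrow(sim$muts),
                           n_screened = sim$n_screened)
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    op <- function(f) file.path(cfg$out_dir, f)
    sorted <- fl$variants[genome_order(fl$variants, cfg$layout), ,
                          drop = FALSE]
    write_vcf(sorted, cfg$layout, op("filtered.vcf"))
    write_windows_tsv(windows, op("windows.tsv"))
    write_regions_bed(regions, op("regions.bed"))
    write_candidates_tsv(candidates, op("candidates.tsv"))
    write_filter_report(fl$report, op("report.json"))
    jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  invisible(list(manifest = manifest, variants = fl$variants,
                 report = fl$report, windows = windows, regions = regions,
                 candidates = candidates, sim = sim))
}
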