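#' Filtering configuration
#'
#' Thresholds and switches for the cascade that extracts high-confidence,
#' presumptive ENU-induced variants from a pooled-sample call set. The
#' defaults mirror standard practice for this mapping strategy: drop calls
#' below Q30, below 5x depth, multiallelic calls, calls at known-variant
#' positions (database or in-house control), calls inside repeat-masked
#' regions, and calls on sex chromosomes. Inequalities are strict: a call
#' at exactly Q30 or exactly 5x passes.
#'
#' @param min_qual Minimum phred site quality (calls with `qual < min_qual`
#'   are removed).
#' @param min_depth Minimum total depth (calls with `depth < min_depth` are
#'   removed).
#' @param biallelic_only Remove multiallelic calls.
#' @param exclude_known Remove calls matching a known-variant set.
#' @param exclude_repeats Remove calls inside repeat-masked intervals.
#' @param exclude_sex_chromosomes Remove calls on the layout's sex
#'   chromosomes.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_qual = 30, min_depth = 5,
                          biallelic_only = TRUE, exclude_known = TRUE,
                          exclude_repeats = TRUE,
                          exclude_sex_chromosomes = TRUE) {
  stopifnot(min_qual >= 0, min_depth >= 0)
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 biallelic_only = isTRUE(biallelic_only),
                 exclude_known = isTRUE(exclude_known),
                 exclude_repeats = isTRUE(exclude_repeats),
                 exclude_sex_chromosomes = isTRUE(exclude_sex_chromosomes)),
            class = "filter_config")
}

filter_rules <- c("known_db", "in_house", "repeat", "low_qual", "low_depth",
                  "multiallelic", "sex_chromosome")

#' Apply the variant filtering cascade
#'
#' A variant passes iff it fails no enabled rule. Each removed variant is
#' attributed to exactly one rule, the first failing one in the fixed order
#' known-database, in-house control, repeat, quality, depth, multiallelic,
#' sex chromosome, so the report is deterministic. Known-variant matching
#' requires chrom + pos + ref + alt identity. Output preserves input order.
#'
#' @param variants A [variant_table()].
#' @param known Optional known-variant set (see [read_known()]): data frame
#'   with columns chrom, pos, ref, alt. Matches count as `known_db`.
#' @param controls Optional second known-variant set of the same shape
#'   (in-house controls); matches count as `in_house`.
#' @param repeats Optional [interval_set()] of repeat-masked regions.
#' @param layout A [genome_layout()] (needed for the sex-chromosome rule).
#' @param cfg A [filter_config()].
#' @return A list with elements `variants` (the passing [variant_table()])
#'   and `report` (a `filter_report`).
#' @export
filter_variants <- function(variants, known = NULL, controls = NULL,
                            repeats = NULL, layout = NULL,
                            cfg = filter_config()) {
  variants <- validate_variant_table(variants)
  stopifnot(inherits(cfg, "filter_config"))
  n <- nrow(variants)
  rule <- rep(NA_character_, n)

  assign_rule <- function(rule, hit, name) {
    rule[is.na(rule) & hit] <- name
    rule
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")

  if (cfg$exclude_known && n) {
    hit_db <- variants$in_known_db
    if (!is.null(known) && nrow(known)) {
      hit_db <- hit_db | key(variants) %in% key(known)
    }
    rule <- assign_rule(rule, hit_db, "known_db")
    if (!is.null(controls) && nrow(controls)) {
      rule <- assign_rule(rule, key(variants) %in% key(controls), "in_house")
    }
  }
  if (cfg$exclude_repeats && n) {
    hit_rep <- variants$in_repeat
    if (!is.null(repeats)) {
      hit_rep <- hit_rep | in_intervals(repeats, variants$chrom,
                                        variants$pos - 1)
    }
    rule <- assign_rule(rule, hit_rep, "repeat")
  }
  if (n) {
    rule <- assign_rule(rule, is.na(variants$qual) |
                          variants$qual < cfg$min_qual, "low_qual")
    rule <- assign_rule(rule, variants$depth < cfg$min_depth, "low_depth")
    if (cfg$biallelic_only) {
      rule <- assign_rule(rule, variants$multiallelic, "multiallelic")
    }
    if (cfg$exclude_sex_chromosomes && !is.null(layout)) {
      rule <- assign_rule(rule,
                          variants$chrom %in% attr(layout, "sex_chromosomes"),
                          "sex_chromosome")
    }
  }

  removed <- vapply(filter_rules, function(r) sum(rule == r, na.rm = TRUE),
                    integer(1))
  report <- structure(c(list(input_count = n), as.list(removed),
                        list(passing_count = sum(is.na(rule)))),
                      class = "filter_report")
  list(variants = variants[is.na(rule), , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Variant filter report:", x$input_count, "in,", x$passing_count,
      "passing\n")
  for (r in filter_rules) {
    if (x[[r]] > 0) cat("  removed ", r, ": ", x[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report A `filter_report` from [filter_variants()].
#' @param path Output file path.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Restrict a variant set to the virtual exome
#'
#' Keeps exactly the variants annotated with an exon-resident or splice-site
#' category ([EXON_RESIDENT_CATEGORIES]), emulating the restriction of a
#' whole-genome call set to what a whole-exome capture would query. UTR,
#' intronic, intergenic and unclassified variants are dropped; unannotated
#' variants (missing category) are excluded with a counted warning. Order is
#' preserved and the operation is idempotent.
#'
#' @param variants A [variant_table()].
#' @return The exon-resident subset, order preserved.
#' @export
virtual_exome <- function(variants) {
  variants <- validate_variant_table(variants)
  unannotated <- sum(is.na(variants$category))
  if (unannotated > 0) {
    warning(unannotated, " unannotated variant(s) excluded from the virtual exome")
  }
  keep <- !is.na(variants$category) &
    variants$category %in% EXON_RESIDENT_CATEGORIES
  variants[keep, , drop = FALSE]
}
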