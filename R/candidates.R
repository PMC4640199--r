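#' Extract candidate causal mutations from mapping regions
#'
#' Keeps the variants that lie inside a called region and carry a damaging
#' functional category ([DAMAGING_CATEGORIES]: non-synonymous, stopgain,
#' stoploss, or splice-site within 10 bp of an exon). Zygosity then
#' narrows the list: under the homozygosity strategy (`require_hom = TRUE`)
#' only variants classed homozygous are kept; under the NAF strategy only
#' variants with pooled NAF at or above `naf_floor`. Unannotated variants
#' inside regions are excluded with a counted warning. Candidates are
#' sorted by descending NAF, ties in genome order, and carry a dense
#' `rank` by NAF (tied NAFs share a rank; in a clean pool every fully
#' linked variant has NAF exactly 1, so rank 1 is shared).
#'
#' @param variants An annotated, filtered [variant_table()].
#' @param regions A region table from [find_regions()].
#' @param naf_floor NAF threshold for the NAF strategy (default 0.7).
#' @param require_hom Use the homozygosity strategy.
#' @param hom_naf_threshold Homozygote classification threshold passed to
#'   [call_zygosity()].
#' @return A data frame of class `candidate_table` with columns gene, naf,
#'   chrom, pos, ref, alt, category, aa_change, zygosity, rank, region
#'   (row index into `regions`).
#' @export
candidate_mutations <- function(variants, regions, naf_floor = 0.7,
                                require_hom = FALSE,
                                hom_naf_threshold = 0.9) {
  variants <- validate_variant_table(variants)
  empty <- data.frame(gene = character(), naf = numeric(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      category = character(), aa_change = character(),
                      zygosity = character(), rank = integer(),
                      region = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("candidate_table", "data.frame")
  if (!nrow(regions) || !nrow(variants)) return(empty)

  region_of <- rep(NA_integer_, nrow(variants))
  for (i in seq_len(nrow(regions))) {
    inside <- variants$chrom == regions$chrom[i] &
      variants$pos - 1 >= regions$start[i] &
      variants$pos - 1 < regions$end[i]
    region_of[inside & is.na(region_of)] <- i
  }
  in_region <- !is.na(region_of)
  unannotated <- in_region & is.na(variants$category)
  if (any(unannotated)) {
    warning(sum(unannotated),
            " unannotated variant(s) inside regions excluded from candidates")
  }
  keep <- in_region & !is.na(variants$category) &
    variants$category %in% DAMAGING_CATEGORIES
  if (!any(keep)) return(empty)

  v <- variants[keep, , drop = FALSE]
  zyg <- call_zygosity(v, hom_naf_threshold)
  if (require_hom) {
    sel <- zyg == "hom"
  } else {
    sel <- v$naf >= naf_floor
  }
  if (!any(sel)) return(empty)
  v <- v[sel, , drop = FALSE]
  out <- data.frame(gene = v$gene, naf = v$naf, chrom = v$chrom,
                    pos = v$pos, ref = v$ref, alt = v$alt,
                    category = v$category, aa_change = v$aa_change,
                    zygosity = zyg[sel], rank = NA_integer_,
                    region = region_of[keep][sel],
                    stringsAsFactors = FALSE)
  ord <- order(-out$naf, out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  out$rank <- match(out$naf, sort(unique(out$naf), decreasing = TRUE))
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' @export
print.candidate_table <- function(x, ...) {
  cat("Candidate causal mutations:", nrow(x), "\n")
  NextMethod()
}

#' Write candidates as TSV
#'
#' Columns: gene, NAF, chrom, bp, ref allele, var allele, category,
#' AA change, zygosity.
#'
#' @param candidates A candidate table from [candidate_mutations()].
#' @param path Output file path.
#' @export
write_candidates_tsv <- function(candidates, path) {
  out <- candidates[, c("gene", "naf", "chrom", "pos", "ref", "alt",
                        "category", "aa_change", "zygosity")]
  names(out) <- c("gene", "NAF", "chrom", "bp", "ref_allele", "var_allele",
                  "category", "AA_change", "zygosity")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype concordance of candidates in follow-up mice
#'
#' Summarizes individual genotyping of candidate mutations in affected and
#' phenotypically wild-type follow-up animals. Per candidate it counts
#' affected mice that are homozygous, affected mice that are not
#' homozygous (discordant), and unaffected mice that are homozygous
#' (discordant). A candidate with any discordant mouse is flagged
#' `excluded`; one with genotype data and no discordance is `concordant`;
#' one without genotype rows is `untested`. Row order of the genotype
#' table never changes the result.
#'
#' @param candidates A candidate table from [candidate_mutations()].
#' @param genotypes Data frame with columns `mouse`, `phenotype`
#'   (`"affected"`/`"unaffected"`), `gene` (matching a candidate's gene
#'   label), `genotype` (`"hom"`, `"het"`, `"wt"`).
#' @return A data frame with one row per candidate: gene, n_affected_hom,
#'   n_affected_not_hom, n_unaffected_hom, status.
#' @export
concordance_table <- function(candidates, genotypes) {
  stopifnot(all(c("mouse", "phenotype", "gene", "genotype") %in%
                  names(genotypes)))
  if (!all(genotypes$phenotype %in% c("affected", "unaffected"))) {
    stop("phenotype must be 'affected' or 'unaffected'")
  }
  if (!all(genotypes$genotype %in% c("hom", "het", "wt"))) {
    stop("genotype must be 'hom', 'het' or 'wt'")
  }
  unknown <- setdiff(unique(genotypes$gene), candidates$gene)
  if (length(unknown)) {
    stop("genotype table names unknown candidate(s): ",
         paste(unknown, collapse = ", "))
  }
  out <- data.frame(gene = candidates$gene, n_affected_hom = 0L,
                    n_affected_not_hom = 0L, n_unaffected_hom = 0L,
                    status = "untested", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    g <- genotypes[genotypes$gene == out$gene[i], , drop = FALSE]
    if (!nrow(g)) next
    aff <- g$phenotype == "affected"
    hom <- g$genotype == "hom"
    out$n_affected_hom[i] <- sum(aff & hom)
    out$n_affected_not_hom[i] <- sum(aff & !hom)
    out$n_unaffected_hom[i] <- sum(!aff & hom)
    discordant <- out$n_affected_not_hom[i] + out$n_unaffected_hom[i]
    out$status[i] <- if (discordant > 0) "excluded" else "concordant"
  }
  out
}
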