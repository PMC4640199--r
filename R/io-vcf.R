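#' Read a pooled-sample SNV VCF
#'
#' Parses a VCF v4.x of SNV calls (vcfR does the parsing) into a
#' [variant_table()], one row per record in input order. Total depth is read
#' from the `DP` INFO key; alternate-read support from `AD` (second value)
#' or, when `AD` is absent, from `DP4` (sum of the two alt-supporting
#' counts). NAF is computed as `alt_depth / depth`. Records without depth
#' information get `depth = 0` and an undefined NAF (with a warning, or an
#' error when `strict = TRUE`). Functional annotations and provenance flags
#' are populated from the reserved INFO keys `EM_GENE`, `EM_CAT`, `EM_AA`,
#' `EM_KNOWN` and `EM_REP` when present.
#'
#' @param path VCF file path (plain text or gzip).
#' @param strict Error (rather than warn) when a record lacks depth fields.
#' @return A [variant_table()] preserving input record order.
#' @export
read_vcf <- function(path, strict = FALSE) {
  check_vcf_structure(path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
                error = function(e) {
                  stop("VCF parse error in '", path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(variant_table())
  }
  info <- fix[, "INFO"]
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  ad <- vcfR::extract.info(v, "AD")
  dp4 <- vcfR::extract.info(v, "DP4")

  alt_depth <- rep(NA_real_, nrow(fix))
  has_ad <- !is.na(ad)
  if (any(has_ad)) {
    alt_depth[has_ad] <- vapply(strsplit(ad[has_ad], ",", fixed = TRUE),
                                function(x) suppressWarnings(as.numeric(x[2])),
                                numeric(1))
  }
  use_dp4 <- is.na(alt_depth) & !is.na(dp4)
  if (any(use_dp4)) {
    alt_depth[use_dp4] <- vapply(strsplit(dp4[use_dp4], ",", fixed = TRUE),
                                 function(x) {
                                   x <- suppressWarnings(as.numeric(x))
                                   if (length(x) >= 4) x[3] + x[4] else NA_real_
                                 }, numeric(1))
  }

  no_depth <- is.na(dp) | is.na(alt_depth)
  if (any(no_depth)) {
    msg <- paste0(sum(no_depth), " record(s) lack depth fields (DP with AD or DP4)")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; assigning depth = 0", call. = FALSE)
    dp[no_depth] <- 0
    alt_depth[no_depth] <- 0
  }

  flag_set <- function(key) grepl(paste0("(^|;)", key, "(;|$|=)"), info)
  gene <- vcfR::extract.info(v, "EM_GENE")
  cat_ <- vcfR::extract.info(v, "EM_CAT")
  aa <- vcfR::extract.info(v, "EM_AA")
  cat_[!is.na(cat_) & !(cat_ %in% VARIANT_CATEGORIES)] <- "unknown"

  alts <- fix[, "ALT"]
  alt1 <- vapply(strsplit(alts, ",", fixed = TRUE), `[[`, character(1), 1L)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  variant_table(chrom = fix[, "CHROM"],
                pos = as.integer(as.numeric(fix[, "POS"])),
                ref = fix[, "REF"], alt = alt1, alts = alts,
                qual = qual, depth = as.integer(dp),
                alt_depth = as.integer(pmin(alt_depth, dp)),
                gene = gene, category = cat_, aa_change = aa,
                in_known_db = flag_set("EM_KNOWN"),
                in_repeat = flag_set("EM_REP"))
}

# Structural pre-check so malformed files fail with a line number, which
# vcfR does not report.
check_vcf_structure <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lineno <- 0L
  seen_header <- FALSE
  first <- TRUE
  repeat {
    chunk <- readLines(con, n = 5000L)
    if (!length(chunk)) break
    for (ln in chunk) {
      lineno <- lineno + 1L
      if (first) {
        if (!startsWith(ln, "##fileformat=VCF")) {
          stop("malformed VCF header at line 1: missing ##fileformat",
               call. = FALSE)
        }
        first <- FALSE
        next
      }
      if (startsWith(ln, "##")) next
      if (startsWith(ln, "#CHROM")) {
        seen_header <- TRUE
        next
      }
      if (!seen_header) {
        stop("malformed VCF header at line ", lineno,
             ": data before #CHROM line", call. = FALSE)
      }
      if (!nzchar(ln)) next
      nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1L]])
      if (nf < 8L) {
        stop("malformed VCF record at line ", lineno, ": ", nf,
             " fields (expected >= 8)", call. = FALSE)
      }
    }
  }
  if (first) stop("malformed VCF header at line 1: empty file", call. = FALSE)
  if (!seen_header) {
    stop("malformed VCF header: no #CHROM line found", call. = FALSE)
  }
  invisible(TRUE)
}

vcf_info_header <- c(
  '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
  '##INFO=<ID=AD,Number=R,Type=Integer,Description="Read depth per allele (ref,alt)">',
  '##INFO=<ID=EM_NAF,Number=1,Type=Float,Description="Non-reference allele frequency (first alt)">',
  '##INFO=<ID=EM_GENE,Number=1,Type=String,Description="Gene symbol">',
  '##INFO=<ID=EM_CAT,Number=1,Type=String,Description="Functional category">',
  '##INFO=<ID=EM_AA,Number=1,Type=String,Description="Amino-acid change">',
  '##INFO=<ID=EM_KNOWN,Number=0,Type=Flag,Description="Present in a known-variant database">',
  '##INFO=<ID=EM_REP,Number=0,Type=Flag,Description="Inside a repeat-masked region">')

#' Write a variant table as VCF v4.2
#'
#' Emits a plain-text VCF with contig header lines from the layout and the
#' package's reserved INFO keys (`DP`, `AD`, `EM_NAF`, `EM_GENE`, `EM_CAT`,
#' `EM_AA`, `EM_KNOWN`, `EM_REP`). Input must already be sorted by the
#' layout's chromosome order and position; unsorted input is an error, never
#' silently sorted.
#'
#' @param variants A [variant_table()].
#' @param layout A [genome_layout()] supplying contig order and lengths.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, layout, path) {
  variants <- validate_variant_table(variants)
  stopifnot(inherits(layout, "genome_layout"))
  if (nrow(variants) && !is_genome_sorted(variants, layout)) {
    stop("variants are not sorted by layout chromosome order and position")
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=enumapper",
              sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                      as.integer(layout$length)),
              vcf_info_header,
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  body <- character(0)
  if (nrow(variants)) {
    info <- sprintf("DP=%d;AD=%d,%d", variants$depth,
                    variants$depth - variants$alt_depth, variants$alt_depth)
    has_naf <- !is.na(variants$naf)
    info[has_naf] <- paste0(info[has_naf],
                            sprintf(";EM_NAF=%.6g", variants$naf[has_naf]))
    add_kv <- function(info, key, val) {
      ok <- !is.na(val)
      info[ok] <- paste0(info[ok], ";", key, "=", val[ok])
      info
    }
    info <- add_kv(info, "EM_GENE", variants$gene)
    info <- add_kv(info, "EM_CAT", variants$category)
    info <- add_kv(info, "EM_AA", variants$aa_change)
    info[variants$in_known_db] <- paste0(info[variants$in_known_db], ";EM_KNOWN")
    info[variants$in_repeat] <- paste0(info[variants$in_repeat], ";EM_REP")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s", variants$chrom,
                    variants$pos, variants$ref, variants$alts,
                    format_qual(variants$qual), info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

format_qual <- function(q) {
  out <- sprintf("%g", q)
  out[is.na(q)] <- "."
  out
}

#' Read a known-variant set
#'
#' Known-variant collections (dbSNP-like databases, in-house controls) are
#' accepted either as VCF or as headerless 4-column TSV
#' (chrom, pos, ref, alt). Matching is by exact chrom + pos + ref + alt
#' identity: a novel alternate allele at a known SNP position is still
#' treated as novel.
#'
#' @param path VCF (`.vcf`/`.vcf.gz`) or TSV file path.
#' @return A data frame with columns chrom, pos, ref, alt.
#' @export
read_known <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- read_vcf_positions(path)
  } else {
    v <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer",
                                          "character", "character"),
                           col.names = c("chrom", "pos", "ref", "alt"))
  }
  v
}

# positions/alleles only; tolerates VCFs without depth fields
read_vcf_positions <- function(path) {
  check_vcf_structure(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  }
  alt1 <- vapply(strsplit(fix[, "ALT"], ",", fixed = TRUE), `[[`,
                 character(1), 1L)
  data.frame(chrom = fix[, "CHROM"], pos = as.integer(as.numeric(fix[, "POS"])),
             ref = fix[, "REF"], alt = alt1, stringsAsFactors = FALSE)
}
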