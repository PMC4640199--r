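#' Interval sets
#'
#' A per-chromosome collection of half-open intervals `[start, end)` in
#' 0-based bp, normalized so that intervals are sorted and non-overlapping.
#' Used for repeat masks, known-position masks and exon models. Normalization
#' merges overlapping and abutting intervals with [IRanges::reduce()]; when
#' the input carries feature names (e.g. gene labels for exons) the raw,
#' un-merged features are kept alongside for annotation.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open coordinates.
#' @param name Optional character vector of feature names (gene labels).
#' @return An object of class `interval_set`.
#' @seealso [read_bed()], [in_intervals()], [annotate_by_intervals()]
#' @export
interval_set <- function(chrom = character(), start = numeric(),
                         end = numeric(), name = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  if (length(start) != n || length(end) != n) {
    stop("chrom, start and end must have equal length")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("interval start >= end at entry ", bad[1L],
         " (", chrom[bad[1L]], ":", start[bad[1L]], "-", end[bad[1L]], ")")
  }
  if (any(start < 0)) stop("interval starts must be >= 0")
  features <- NULL
  if (!is.null(name) && n > 0) {
    features <- data.frame(chrom = chrom, start = start, end = end,
                           name = as.character(name), stringsAsFactors = FALSE)
  }
  merged <- list()
  for (ch in unique(chrom)) {
    i <- chrom == ch
    # IRanges is 1-based closed: [start, end) in 0-based == [start+1, end] 1-based;
    # reduce() then merges overlapping and abutting runs.
    ir <- IRanges::reduce(IRanges::IRanges(start = start[i] + 1, end = end[i]))
    merged[[ch]] <- data.frame(start = IRanges::start(ir) - 1,
                               end = IRanges::end(ir))
  }
  structure(list(intervals = merged, features = features),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  n <- sum(vapply(x$intervals, nrow, integer(1)))
  bp <- sum(vapply(x$intervals, function(d) sum(d$end - d$start), numeric(1)))
  cat("Interval set:", n, "merged intervals on", length(x$intervals),
      "chromosomes,", format(bp, big.mark = ","), "bp\n")
  if (!is.null(x$features)) {
    cat("Carries", nrow(x$features), "named features\n")
  }
  invisible(x)
}

#' Number of merged intervals in a set
#' @param iset An [interval_set()].
#' @export
n_intervals <- function(iset) {
  stopifnot(inherits(iset, "interval_set"))
  sum(vapply(iset$intervals, nrow, integer(1)))
}

#' Point membership in an interval set
#'
#' Tests whether 0-based positions fall inside any interval of the set,
#' by binary search (`findInterval`) over the merged, sorted intervals.
#'
#' @param iset An [interval_set()].
#' @param chrom Character vector of chromosome names.
#' @param pos0 Numeric vector of 0-based positions (recycled against `chrom`).
#' @return Logical vector.
#' @export
in_intervals <- function(iset, chrom, pos0) {
  stopifnot(inherits(iset, "interval_set"))
  n <- max(length(chrom), length(pos0))
  chrom <- rep_len(as.character(chrom), n)
  pos0 <- rep_len(as.numeric(pos0), n)
  out <- logical(n)
  for (ch in unique(chrom)) {
    ivl <- iset$intervals[[ch]]
    if (is.null(ivl) || nrow(ivl) == 0L) next
    i <- which(chrom == ch)
    k <- findInterval(pos0[i], ivl$start)
    out[i] <- k > 0L & pos0[i] < ivl$end[pmax(k, 1L)]
  }
  out
}

#' Read a BED file into an interval set
#'
#' Accepts 3+ column BED (0-based half-open). Column 4, when present, is
#' kept as the feature name (used as the gene label by
#' [annotate_by_intervals()]). Lines with `start >= end` raise an error
#' naming the offending line. `track`/`browser` lines and `#` comments are
#' skipped.
#'
#' @param path File path.
#' @return An [interval_set()]; empty files give an empty set.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(interval_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", lineno[which(nf < 3L)[1L]], " has fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("BED line ", lineno[which(is.na(start) | is.na(end))[1L]],
         ": non-numeric start/end")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED line ", lineno[bad[1L]], ": start >= end (",
         start[bad[1L]], " >= ", end[bad[1L]], ")")
  }
  name <- NULL
  if (all(nf >= 4L)) name <- vapply(fields, `[[`, character(1), 4L)
  interval_set(chrom, start, end, name = name)
}

#' Write an interval set as BED
#'
#' Writes the merged intervals (or, when present, the named raw features)
#' as 3- or 4-column BED.
#'
#' @param iset An [interval_set()].
#' @param path Output file path.
#' @export
write_bed <- function(iset, path) {
  stopifnot(inherits(iset, "interval_set"))
  if (!is.null(iset$features)) {
    df <- iset$features[order(iset$features$chrom, iset$features$start), ]
    writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                       as.integer(df$end), df$name), path)
  } else {
    rows <- character(0)
    for (ch in names(iset$intervals)) {
      d <- iset$intervals[[ch]]
      if (nrow(d)) {
        rows <- c(rows, sprintf("%s\t%d\t%d", ch, as.integer(d$start),
                                as.integer(d$end)))
      }
    }
    writeLines(rows, path)
  }
  invisible(path)
}
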