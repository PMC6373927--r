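# Duplication metrics in a Picard-style, MultiQC-readable text format.

METRICS_FIELDS <- c("LIBRARY", "UNPAIRED_READS_EXAMINED", "READ_PAIRS_EXAMINED",
                    "SECONDARY_OR_SUPPLEMENTARY_RDS", "UNMAPPED_READS",
                    "UNPAIRED_READ_DUPLICATES", "READ_PAIR_DUPLICATES",
                    "READ_PAIR_OPTICAL_DUPLICATES", "PERCENT_DUPLICATION",
                    "ESTIMATED_LIBRARY_SIZE")

#' Compute duplication metrics
#'
#' Per-library statistics of a duplicate-marked file:
#' UNPAIRED_READS_EXAMINED and READ_PAIRS_EXAMINED count the examined
#' fragments and pairs; UNPAIRED_READ_DUPLICATES and READ_PAIR_DUPLICATES
#' the ones marked; SECONDARY_OR_SUPPLEMENTARY_RDS and UNMAPPED_READS count
#' the skipped records; READ_PAIR_OPTICAL_DUPLICATES comes from
#' [markOpticalDuplicates()] (0 when optical marking was not run).
#' PERCENT_DUPLICATION = (UNPAIRED_READ_DUPLICATES + 2 *
#' READ_PAIR_DUPLICATES) / (UNPAIRED_READS_EXAMINED + 2 *
#' READ_PAIRS_EXAMINED). ESTIMATED_LIBRARY_SIZE follows Picard:
#' [estimateLibrarySize()] with N = pairs examined minus optical
#' duplicates, U = pairs examined minus pair duplicates.
#'
#' Library rows are ordered by first appearance in the header \code{@RG}
#' dictionary; libraries seen only in records come after, alphabetically.
#'
#' @param dup result of [markDuplicates()].
#' @param sam the marked [SamFile-class] (for unmapped/secondary counts).
#' @param optical optional named vector from [markOpticalDuplicates()].
#' @return data.frame, one row per library, columns as in the Picard
#'   DuplicationMetrics class.
#' @export
computeDuplicationMetrics <- function(dup, sam, optical = NULL) {
  aln <- sam@alignments
  lib <- .recordLibraries(aln, sam@header)
  flag <- aln$flag
  headerLibs <- unique(unname(rgLibraries(sam@header)))
  headerLibs <- headerLibs[!is.na(headerLibs)]
  seen <- unique(c(dup$pairs$lib, dup$fragments$lib,
                   lib[isUnmapped(flag) | isSecondary(flag) |
                       isSupplementary(flag)]))
  libs <- c(headerLibs, sort(setdiff(seen, headerLibs)))
  if (!length(libs)) libs <- character(0)
  cnt <- function(x, w = NULL)
    vapply(libs, function(l) sum((if (is.null(w)) x == l else w[x == l])),
           numeric(1))
  upe <- cnt(dup$fragments$lib)
  rpe <- cnt(dup$pairs$lib)
  upd <- cnt(dup$fragments$lib, dup$fragments$isDup)
  rpd <- cnt(dup$pairs$lib, dup$pairs$isDup)
  sec <- vapply(libs, function(l)
    sum(lib == l & (isSecondary(flag) | isSupplementary(flag))), numeric(1))
  unm <- vapply(libs, function(l) sum(lib == l & isUnmapped(flag)), numeric(1))
  opt <- if (is.null(optical)) setNames(numeric(length(libs)), libs)
         else vapply(libs, function(l)
           if (l %in% names(optical)) optical[[l]] else 0, numeric(1))
  denom <- upe + 2 * rpe
  pct <- ifelse(denom > 0, (upd + 2 * rpd) / denom, 0)
  els <- vapply(seq_along(libs), function(i)
    estimateLibrarySize(rpe[i] - opt[i], rpe[i] - rpd[i]), numeric(1))
  data.frame(LIBRARY = libs,
             UNPAIRED_READS_EXAMINED = upe,
             READ_PAIRS_EXAMINED = rpe,
             SECONDARY_OR_SUPPLEMENTARY_RDS = sec,
             UNMAPPED_READS = unm,
             UNPAIRED_READ_DUPLICATES = upd,
             READ_PAIR_DUPLICATES = rpd,
             READ_PAIR_OPTICAL_DUPLICATES = opt,
             PERCENT_DUPLICATION = pct,
             ESTIMATED_LIBRARY_SIZE = els,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a duplication metrics file
#'
#' Emits a "## METRICS CLASS" section with a tab-separated header row and
#' one row per library, PERCENT_DUPLICATION with 6 decimal places and
#' ESTIMATED_LIBRARY_SIZE blank when undefined -- structurally the Picard
#' metrics layout that MultiQC parses.
#'
#' @param metrics data.frame from [computeDuplicationMetrics()].
#' @param path output path or connection.
#' @return invisibly, the path.
#' @export
writeMetrics <- function(metrics, path) {
  rows <- vapply(seq_len(nrow(metrics)), function(i) {
    m <- metrics[i, ]
    paste(m$LIBRARY,
          sprintf("%.0f", m$UNPAIRED_READS_EXAMINED),
          sprintf("%.0f", m$READ_PAIRS_EXAMINED),
          sprintf("%.0f", m$SECONDARY_OR_SUPPLEMENTARY_RDS),
          sprintf("%.0f", m$UNMAPPED_READS),
          sprintf("%.0f", m$UNPAIRED_READ_DUPLICATES),
          sprintf("%.0f", m$READ_PAIR_DUPLICATES),
          sprintf("%.0f", m$READ_PAIR_OPTICAL_DUPLICATES),
          sprintf("%.6f", m$PERCENT_DUPLICATION),
          if (is.na(m$ESTIMATED_LIBRARY_SIZE)) "" else
            sprintf("%.0f", round(m$ESTIMATED_LIBRARY_SIZE)),
          sep = "\t")
  }, character(1))
  writeLines(c("## METRICS CLASS\tDuplicationMetrics",
               paste(METRICS_FIELDS, collapse = "\t"),
               rows, ""), path)
  invisible(path)
}

#' Read a duplication metrics file
#'
#' Parses the output of [writeMetrics()] back into a data.frame (blank
#' ESTIMATED_LIBRARY_SIZE becomes NA).
#'
#' @param path metrics file path.
#' @return data.frame with the Picard DuplicationMetrics columns.
#' @export
readMetrics <- function(path) {
  lines <- readLines(path)
  hdr <- which(lines == paste(METRICS_FIELDS, collapse = "\t"))
  if (!length(hdr)) stop("metrics parse error: field header not found")
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nzchar(body)]
  if (!length(body))
    return(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(METRICS_FIELDS))),
      METRICS_FIELDS))
  f <- strsplit(body, "\t", fixed = TRUE)
  getf <- function(i) vapply(f, function(x)
    if (length(x) >= i) x[i] else "", character(1))
  df <- data.frame(LIBRARY = getf(1), stringsAsFactors = FALSE)
  for (i in 2:8) df[[METRICS_FIELDS[i]]] <- as.numeric(getf(i))
  df$PERCENT_DUPLICATION <- as.numeric(getf(9))
  els <- getf(10)
  df$ESTIMATED_LIBRARY_SIZE <- ifelse(nzchar(els), suppressWarnings(as.numeric(els)), NA_real_)
  df
}
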