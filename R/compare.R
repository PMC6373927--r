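# Deterministic output comparison: the normalization recipe that makes two
# tools' outputs diff-able -- strip program lines/tags (which legitimately
# differ), sort each record's optional fields (their order is unspecified),
# then sort whole lines so residual ordering ties cancel out.

#' Normalize a SamFile for exact comparison
#'
#' Removes \code{@PG} header lines and \code{PG} optional tags, sorts each
#' record's optional fields by tag name, and returns all lines (header
#' then records) sorted byte-lexicographically.
#'
#' @param sam a [SamFile-class].
#' @return character vector of normalized, sorted lines.
#' @export
normalizeSam <- function(sam) {
  hdr <- sam@header@lines
  hdr <- hdr[!startsWith(hdr, "@PG")]
  aln <- sam@alignments
  if (nrow(aln)) {
    hasTags <- nzchar(aln$tags)
    aln$tags[hasTags] <- vapply(aln$tags[hasTags], function(t) {
      f <- strsplit(t, "\t", fixed = TRUE)[[1L]]
      f <- f[!startsWith(f, "PG:")]
      paste(sort(f, method = "radix"), collapse = "\t")
    }, character(1), USE.NAMES = FALSE)
  }
  tmp <- sam
  tmp@header <- new("SamHeader", lines = character(0))
  tmp@alignments <- aln
  body <- samLines(tmp)
  sort(c(hdr, body), method = "radix")
}

#' Compare two SAM files after normalization
#'
#' Applies [normalizeSam()] to both sides and reports whether they are
#' identical; if not, the first differing line of each side is included.
#'
#' @param a,b SAM paths, [samText()] objects or [SamFile-class] objects.
#' @return list: \code{equal} (logical), \code{nA}, \code{nB} (line
#'   counts), \code{firstDiff} (NULL, or list(line, a, b)).
#' @export
compareSams <- function(a, b) {
  la <- normalizeSam(if (is(a, "SamFile")) a else readSam(a))
  lb <- normalizeSam(if (is(b, "SamFile")) b else readSam(b))
  if (identical(la, lb))
    return(list(equal = TRUE, nA = length(la), nB = length(lb),
                firstDiff = NULL))
  nmin <- min(length(la), length(lb))
  diffAt <- which(la[seq_len(nmin)] != lb[seq_len(nmin)])
  at <- if (length(diffAt)) diffAt[1L] else nmin + 1L
  list(equal = FALSE, nA = length(la), nB = length(lb),
       firstDiff = list(line = at,
                        a = if (at <= length(la)) la[at] else "<absent>",
                        b = if (at <= length(lb)) lb[at] else "<absent>"))
}
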