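# Whole-set sorting operations (phase 2).

#' Sort a SamFile by coordinate
#'
#' Orders records by (index of rname in the header @SQ dictionary, pos
#' ascending); unmapped records (rname "*") go after all mapped records.
#' Ties are broken by \code{fileIndex}, making the sort stable and the
#' output independent of how any underlying sort handles ties. The header
#' SO field is set to "coordinate". A mapped record whose rname is not
#' in the sequence dictionary is an error.
#'
#' @param sam a [SamFile-class].
#' @return the sorted [SamFile-class].
#' @export
sortCoordinate <- function(sam) {
  aln <- sam@alignments
  sq <- sqNames(sam@header)
  idx <- match(aln$rname, sq)
  badMapped <- aln$rname != "*" & is.na(idx)
  if (any(badMapped))
    stop("record rname not in @SQ: ", aln$rname[which(badMapped)[1L]])
  o <- order(idx, aln$pos, aln$fileIndex, method = "radix", na.last = TRUE)
  sam@alignments <- aln[o, , drop = FALSE]
  rownames(sam@alignments) <- NULL
  sam@header <- setSortOrder(sam@header, "coordinate")
  sam
}

#' Sort a SamFile by query name
#'
#' Groups and orders records by qname in plain byte-lexicographic order
#' (not Picard's numeric-aware "natural" order), ties broken by
#' \code{fileIndex}. The header SO field is set to "queryname". When both
#' sides of a comparison are sorted by this same function the ordering
#' choice cancels out, which is what the deterministic comparison recipe
#' relies on.
#'
#' @param sam a [SamFile-class].
#' @return the sorted [SamFile-class].
#' @export
sortQueryname <- function(sam) {
  aln <- sam@alignments
  o <- order(aln$qname, aln$fileIndex, method = "radix")
  sam@alignments <- aln[o, , drop = FALSE]
  rownames(sam@alignments) <- NULL
  sam@header <- setSortOrder(sam@header, "queryname")
  sam
}
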