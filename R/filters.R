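# Stock per-record filters for phases 1 and 3.
#
# A filter is a two-level closure mirroring the engine contract: a
# header-stage function that may rewrite the header and returns the
# per-record stage. The per-record stage receives a block of alignment rows
# and returns list(keep = logical, aln = possibly modified rows). Per-record
# decisions must not depend on neighbouring records -- that independence is
# what lets the engine merge filters into one pass and apply them to record
# shards in any partition.

#' Construct a filter
#'
#' @param name display name used in run reports.
#' @param headerFn function(header) -> list(header = SamHeader,
#'   recordFn = function(aln) list(keep, aln) or NULL).
#' @return a "samFilter" object.
#' @export
samFilter <- function(name, headerFn) {
  structure(list(name = name, headerFn = headerFn), class = "samFilter")
}

.keepAll <- function(aln) list(keep = rep(TRUE, nrow(aln)), aln = aln)

#' Filter out unmapped reads
#'
#' Removes records with the unmapped flag bit (0x4) set.
#'
#' @return a "samFilter".
#' @export
filterUnmapped <- function() {
  samFilter("filter-unmapped", function(header) {
    list(header = header, recordFn = function(aln)
      list(keep = !isUnmapped(aln$flag), aln = aln))
  })
}

#' Filter reads by target regions
#'
#' Keeps a mapped record iff its reference span (pos to
#' pos + reference length of the CIGAR - 1, 1-based inclusive, where the
#' reference length counts M/D/N/=/X operators) overlaps any interval of
#' its contig; soft/hard clips are excluded from the span, matching the
#' "-L" conventions of SAMtools/Picard/GATK. Unmapped records, and records
#' on contigs absent from the region set, are removed. Mate rescue (keeping
#' a read because its mate overlaps) is off by default and not part of this
#' filter.
#'
#' @param regions a [RegionSet-class].
#' @return a "samFilter".
#' @export
filterRegions <- function(regions) {
  stopifnot(is(regions, "RegionSet"))
  samFilter("filter-regions", function(header) {
    list(header = header, recordFn = function(aln) {
      if (!nrow(aln)) return(.keepAll(aln))
      mapped <- !isUnmapped(aln$flag)
      keep <- rep(FALSE, nrow(aln))
      if (any(mapped)) {
        refLen <- cigarRefLength(aln$cigar[mapped])
        ends <- aln$pos[mapped] + pmax(refLen - 1L, 0L)
        keep[mapped] <- regionOverlaps(regions, aln$rname[mapped],
                                       aln$pos[mapped], ends)
      }
      list(keep = keep, aln = aln)
    })
  })
}

#' Filter out duplicate-flagged reads
#'
#' Phase-3 companion to duplicate marking: removes records with flag bit
#' 0x400 set. A no-op on files that were never marked.
#'
#' @return a "samFilter".
#' @export
filterRemoveDuplicates <- function() {
  samFilter("remove-duplicates", function(header) {
    list(header = header, recordFn = function(aln)
      list(keep = !isDuplicate(aln$flag), aln = aln))
  })
}
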