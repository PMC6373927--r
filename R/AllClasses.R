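#' @import methods
#' @importFrom stats dbinom dnorm setNames
#' @importFrom utils head tail
#' @importFrom data.table data.table as.data.table rbindlist setorderv
NULL

ALN_COLUMNS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "rnext", "pnext", "tlen", "seq", "qual", "tags", "fileIndex")

#' SAM header
#'
#' Lossless container for the header section of a SAM file. The raw header
#' lines are kept verbatim so that parse/write round trips are byte-exact;
#' structured views (\code{@SQ} names and lengths, \code{@RG} dictionaries,
#' the \code{SO} sort-order field) are parsed on demand by the accessors.
#'
#' @slot lines character vector of raw header lines (each starting with "@").
#' @seealso [sqNames()], [sortOrder()], [rgLibraries()]
#' @export
setClass("SamHeader", representation(lines = "character"))

setValidity("SamHeader", function(object) {
  if (length(object@lines) && !all(startsWith(object@lines, "@")))
    return("all header lines must start with '@'")
  sq <- sqNames(object)
  if (anyDuplicated(sq)) return("@SQ names must be unique")
  rg <- .rgField(object, "ID")
  if (anyDuplicated(rg[!is.na(rg)])) return("@RG IDs must be unique")
  TRUE
})

#' In-memory SAM file
#'
#' The central container of the engine: a [SamHeader-class] plus an ordered
#' table of alignment records, one row per SAM alignment line. Columns follow
#' the SAM mandatory fields (\code{qname}, \code{flag}, \code{rname},
#' \code{pos}, \code{mapq}, \code{cigar}, \code{rnext}, \code{pnext},
#' \code{tlen}, \code{seq}, \code{qual}); optional tag fields are kept as the
#' verbatim tab-joined string in \code{tags} so that tag order survives a
#' round trip. \code{fileIndex} is the 0-based ordinal of the record among
#' the alignment lines of the original input and acts as the stable
#' tie-break key throughout the engine (sorting stability, deterministic
#' duplicate-survivor selection).
#'
#' Coordinates use the SAM convention: \code{pos} is 1-based inclusive and
#' 0 means unavailable.
#'
#' @slot header a [SamHeader-class].
#' @slot alignments data.frame with the columns listed above.
#' @seealso [readSam()], [writeSam()], [alignments()]
#' @export
setClass("SamFile", representation(header = "SamHeader", alignments = "data.frame"))

setValidity("SamFile", function(object) {
  aln <- object@alignments
  missing <- setdiff(ALN_COLUMNS, names(aln))
  if (length(missing))
    return(paste("missing alignment columns:", paste(missing, collapse = ", ")))
  if (nrow(aln)) {
    if (any(aln$pos < 0, na.rm = TRUE)) return("pos must be >= 0")
    both <- aln$seq != "*" & aln$qual != "*"
    if (any(nchar(aln$seq[both]) != nchar(aln$qual[both])))
      return("seq and qual lengths differ for a record where both are present")
  }
  TRUE
})

#' Genomic region set
#'
#' Target intervals loaded from a BED file, stored 0-based half-open and
#' normalized per contig (sorted, overlapping/adjacent intervals merged via
#' \code{IRanges::reduce}).
#'
#' @slot regions named list, one \code{IRanges} per contig (1-based closed
#'   internally; converted from BED on load).
#' @seealso [readBed()], [filterRegions()]
#' @export
setClass("RegionSet", representation(regions = "list"))

#' Known polymorphic sites
#'
#' Positions (e.g. dbSNP) excluded from base quality score recalibration
#' error counting. Each site carries a span: for a deletion allele the whole
#' REF footprint is masked; multi-allelic lines contribute the longest REF
#' span.
#'
#' @slot sites data.frame with columns \code{contig}, \code{pos} (1-based),
#'   \code{span} (>= 1); sorted and unique per contig.
#' @seealso [readVcfSites()], [bqsrTabulate()]
#' @export
setClass("KnownSites", representation(sites = "data.frame"))

setValidity("KnownSites", function(object) {
  s <- object@sites
  if (!all(c("contig", "pos", "span") %in% names(s)))
    return("sites must have contig/pos/span columns")
  if (nrow(s) && any(s$span < 1)) return("span must be >= 1")
  if (nrow(s)) {
    o <- order(s$contig, s$pos, method = "radix")
    if (!identical(o, seq_len(nrow(s)))) return("sites must be sorted by contig, pos")
    if (any(duplicated(s[c("contig", "pos")]))) return("sites must be unique per contig")
  }
  TRUE
})

#' Recalibration table
#'
#' Hierarchical mismatch counts per covariate bin, as produced by
#' [bqsrTabulate()]: a global bin per read group, a bin per (read group,
#' reported quality), and sub-bins per cycle and per sequence context.
#' Each bin holds observation and error (mismatch) counts; after
#' [computeDeltas()] each level additionally carries its empirical quality
#' and quality delta. Counts are conserved across levels: a parent bin's
#' counts equal the sum of its children's.
#'
#' @slot global data.frame per read group: \code{rg}, \code{obs},
#'   \code{err}, \code{sumQ} (exact sum of reported qualities, so chunked
#'   tabulations reduce without rounding); after [computeDeltas()] also
#'   \code{empQ}, \code{delta} and \code{estQ} (= sumQ/obs, the
#'   count-weighted mean reported quality).
#' @slot byQ data.frame per (rg, reported quality q).
#' @slot byCycle data.frame per (rg, q, cycle); cycle is signed (negated for
#'   second-of-pair reads).
#' @slot byContext data.frame per (rg, q, context).
#' @slot params list: \code{sigma} (Gaussian prior width on the Phred
#'   scale), \code{context} (number of preceding bases), \code{hasDeltas}.
#' @export
setClass("RecalTable", representation(
  global = "data.frame", byQ = "data.frame",
  byCycle = "data.frame", byContext = "data.frame",
  params = "list"))

#' Pipeline plan
#'
#' The canonical three-phase execution plan derived from an option set by
#' [buildPlan()]. Construction is a pure function of the option values:
#' permuting the order in which options are given yields an identical plan.
#'
#' @slot phase1 character vector of filter names applied while reading, in
#'   canonical order (filters are instantiated at run time from the
#'   options, keeping plans directly comparable).
#' @slot phase2 character vector of whole-set operations in canonical order
#'   (subset of \code{c("sort", "markDuplicates", "bqsrTabulate")}).
#' @slot phase3 character vector of output-time steps in canonical order.
#' @slot options canonicalized named option list.
#' @export
setClass("PipelinePlan", representation(
  phase1 = "character", phase2 = "character", phase3 = "character",
  options = "list"))

setMethod("show", "SamHeader", function(object) {
  cat("SamHeader:", length(object@lines), "lines;",
      length(sqNames(object)), "@SQ;",
      sum(startsWith(object@lines, "@RG")), "@RG\n")
})

setMethod("show", "SamFile", function(object) {
  aln <- object@alignments
  cat("SamFile with", nrow(aln), "alignments over",
      length(sqNames(object@header)), "reference sequences",
      paste0("(SO:", sortOrder(object@header), ")\n"))
  if (nrow(aln)) {
    cat("  mapped:", sum(!isUnmapped(aln$flag)),
        " duplicates flagged:", sum(isDuplicate(aln$flag)), "\n")
  }
})

setMethod("show", "RegionSet", function(object) {
  n <- vapply(object@regions, length, integer(1))
  cat("RegionSet:", sum(n), "intervals on", length(n), "contigs\n")
})

setMethod("show", "KnownSites", function(object) {
  cat("KnownSites:", nrow(object@sites), "sites on",
      length(unique(object@sites$contig)), "contigs\n")
})

setMethod("show", "RecalTable", function(object) {
  cat("RecalTable:", nrow(object@global), "read groups,",
      nrow(object@byQ), "quality bins,",
      nrow(object@byCycle), "cycle bins,",
      nrow(object@byContext), "context bins",
      if (isTRUE(object@params$hasDeltas)) "(deltas computed)" else "(counts only)",
      "\n")
})

setMethod("show", "PipelinePlan", function(object) {
  cat("PipelinePlan\n",
      " phase 1:", paste(object@phase1, collapse = ", "), "\n",
      " phase 2:", paste(object@phase2, collapse = ", "), "\n",
      " phase 3:", paste(object@phase3, collapse = ", "), "\n")
})

#' Access the alignment table of a SamFile
#'
#' @param x a [SamFile-class].
#' @return data.frame of alignment records.
#' @export
alignments <- function(x) {
  stopifnot(is(x, "SamFile"))
  x@alignments
}

#' Replace the alignment table of a SamFile
#'
#' @param x a [SamFile-class].
#' @param value replacement data.frame with the standard columns.
#' @return the modified SamFile.
#' @export
`alignments<-` <- function(x, value) {
  x@alignments <- as.data.frame(value)
  rownames(x@alignments) <- NULL
  validObject(x)
  x
}

#' Access the header of a SamFile
#' @param x a [SamFile-class].
#' @return the [SamHeader-class].
#' @export
samHeader <- function(x) {
  stopifnot(is(x, "SamFile"))
  x@header
}

#' @rdname samHeader
#' @param value replacement [SamHeader-class].
#' @export
`samHeader<-` <- function(x, value) {
  x@header <- value
  validObject(x)
  x
}
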