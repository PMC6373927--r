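# Duplicate marking with Picard-compatible semantics, optical duplicate
# clustering on flow-cell coordinates, and the library-size estimator.
#
# Reads are grouped into duplicate classes by library and adapted
# (unclipped) 5' position/orientation. Records with both ends mapped and
# paired form pair classes keyed by both ends; remaining mapped primary
# records form fragment classes. A fragment whose key coincides with any
# pair-class end is always a duplicate (pairs beat fragments). Within a
# class the best-scoring record survives; everything else gets flag 0x400.

#' Unclipped (adapted) 5' position
#'
#' The duplicate-key coordinate: the alignment position after undoing
#' soft/hard clipping at the read's 5' end. Forward strand:
#' pos - leading clip lengths. Reverse strand:
#' pos + reference length(CIGAR) - 1 + trailing clip lengths, where the
#' reference length counts M/D/N/=/X. 1-based.
#'
#' @param x a [SamFile-class] or alignment data.frame.
#' @return integer vector, one value per record.
#' @export
unclippedPosition <- function(x) {
  aln <- if (is(x, "SamFile")) x@alignments else x
  if (any(isUnmapped(aln$flag)))
    stop("unclippedPosition is undefined for unmapped records")
  clips <- .clipLengths(aln$cigar)
  refLen <- cigarRefLength(aln$cigar)
  ifelse(isReverse(aln$flag),
         aln$pos + refLen - 1L + clips$trail,
         aln$pos - clips$lead)
}

#' Record quality score for duplicate ranking
#'
#' Sum of the base quality values that are >= 15 (Picard's default
#' summation rule). A missing quality string ("*") scores 0. For a pair the
#' pair score is the sum of both mates' scores.
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return numeric vector of scores.
#' @export
recordScore <- function(qual) {
  vapply(qual, function(q) {
    if (q == "*") return(0)
    v <- utf8ToInt(q) - 33L
    sum(v[v >= 15L])
  }, numeric(1), USE.NAMES = FALSE)
}

# library of each record: RG tag -> @RG LB, else "Unknown Library"
.recordLibraries <- function(aln, header) {
  libs <- rgLibraries(header)
  rg <- getTagValue(aln$tags, "RG")
  lib <- unname(libs[rg])
  lib[is.na(lib)] <- "Unknown Library"
  lib
}

# canonical pair end ordering: by (contig index, unclipped pos, strand)
.endLE <- function(c1, p1, s1, c2, p2, s2) {
  (c1 < c2) | (c1 == c2 & (p1 < p2 | (p1 == p2 & s1 <= s2)))
}

#' Mark duplicate reads
#'
#' Classifies mapped primary records into duplicate classes and sets or
#' clears flag bit 0x400 accordingly. Secondary, supplementary and unmapped
#' records are never examined and never selected as survivors; their flags
#' are left untouched. Within a class the survivor is the highest-scoring
#' member ([recordScore()]; pair score = sum of mates); score ties go to
#' the lowest \code{fileIndex} when \code{deterministic} (the
#' non-deterministic mode uses the same rule, which is one of the allowed
#' outcomes). Paired records whose mate is absent from the file are treated
#' as fragments and reported in the result's \code{warnings}.
#'
#' @param sam a [SamFile-class].
#' @param deterministic logical; tie-break by file order so repeated runs
#'   are byte-identical. The order used is the record ordinal in the
#'   current record table -- for a freshly parsed file that is exactly
#'   \code{fileIndex}, and after an in-memory sort it matches the ordinal
#'   the record would have if the sorted file were written out and read
#'   back, which keeps the merged single-pass pipeline byte-identical to
#'   running the steps as separate chained invocations.
#' @param externalPairKeys character vector of additional single-end pair
#'   keys (used by the split-filter-merge mode so the pairs-beat-fragments
#'   rule sees pair classes living in other chunks).
#' @return list with elements \code{sam} (flags updated), \code{pairs}
#'   (one row per examined pair: library, read group, class key, score,
#'   survivor/duplicate status, mate row indices, qname), \code{fragments}
#'   (one row per examined fragment), \code{pairEndKeys} (single-end keys
#'   covered by pair classes, for cross-chunk sharing), and
#'   \code{warnings}.
#' @export
markDuplicates <- function(sam, deterministic = TRUE,
                           externalPairKeys = character(0)) {
  aln <- sam@alignments
  n <- nrow(aln)
  warnings <- character(0)
  empty <- function(...) data.frame(...)
  if (!n) {
    return(list(sam = sam,
                pairs = empty(lib = character(0), rg = character(0),
                              key = character(0), qname = character(0),
                              score = numeric(0), pairIndex = integer(0),
                              row1 = integer(0), row2 = integer(0),
                              isDup = logical(0)),
                fragments = empty(lib = character(0), key = character(0),
                                  qname = character(0), score = numeric(0),
                                  row = integer(0), isDup = logical(0)),
                pairEndKeys = character(0), warnings = warnings))
  }
  flag <- aln$flag
  eligible <- !isUnmapped(flag) & !isSecondary(flag) & !isSupplementary(flag)
  lib <- .recordLibraries(aln, sam@header)
  rg <- getTagValue(aln$tags, "RG")
  sq <- sqNames(sam@header)
  contigIdx <- match(aln$rname, sq)
  ucp <- rep(NA_integer_, n)
  mapped <- !isUnmapped(flag)
  ucp[mapped] <- unclippedPosition(aln[mapped, , drop = FALSE])
  strand <- ifelse(isReverse(flag), "R", "F")
  score <- recordScore(aln$qual)

  # --- pair candidates: paired, both this record and its mate mapped ---
  pairCand <- which(eligible & isPaired(flag) & !isMateUnmapped(flag))
  cnt <- table(aln$qname[pairCand])
  pairedNames <- names(cnt)[cnt == 2L]
  lone <- pairCand[!(aln$qname[pairCand] %in% pairedNames)]
  if (length(lone))
    warnings <- c(warnings, sprintf(
      "%d paired record(s) without a usable mate in the file; treated as fragments",
      length(lone)))
  inPair <- pairCand[aln$qname[pairCand] %in% pairedNames]

  pairs <- NULL
  pairEndKeys <- character(0)
  if (length(inPair)) {
    o <- inPair[order(aln$qname[inPair], inPair, method = "radix")]
    r1 <- o[seq(1L, length(o), by = 2L)]
    r2 <- o[seq(2L, length(o), by = 2L)]
    swap <- !.endLE(contigIdx[r1], ucp[r1], strand[r1],
                    contigIdx[r2], ucp[r2], strand[r2])
    a <- ifelse(swap, r2, r1)
    b <- ifelse(swap, r1, r2)
    key <- paste(lib[a], contigIdx[a], ucp[a], strand[a],
                 contigIdx[b], ucp[b], strand[b], sep = "|")
    pairs <- data.frame(
      lib = lib[a], rg = ifelse(is.na(rg[a]), "", rg[a]), key = key,
      qname = aln$qname[a],
      score = score[a] + score[b],
      pairIndex = pmin(a, b),
      row1 = a, row2 = b, stringsAsFactors = FALSE)
    pairEndKeys <- unique(c(
      paste(lib[a], contigIdx[a], ucp[a], strand[a], sep = "|"),
      paste(lib[b], contigIdx[b], ucp[b], strand[b], sep = "|")))
    # survivor per class: max score, tie -> lowest pair file index
    po <- order(pairs$key, -pairs$score, pairs$pairIndex, method = "radix")
    first <- !duplicated(pairs$key[po])
    isDup <- logical(nrow(pairs))
    isDup[po] <- !first
    pairs$isDup <- isDup
  } else {
    pairs <- empty(lib = character(0), rg = character(0), key = character(0),
                   qname = character(0), score = numeric(0),
                   pairIndex = integer(0), row1 = integer(0),
                   row2 = integer(0), isDup = logical(0))
  }

  # --- fragments: remaining eligible mapped primaries ---
  fragRows <- setdiff(which(eligible & mapped), inPair)
  if (length(fragRows)) {
    fkey <- paste(lib[fragRows], contigIdx[fragRows], ucp[fragRows],
                  strand[fragRows], sep = "|")
    beaten <- fkey %in% c(pairEndKeys, externalPairKeys)
    fragments <- data.frame(
      lib = lib[fragRows], key = fkey, qname = aln$qname[fragRows],
      score = score[fragRows], row = fragRows,
      stringsAsFactors = FALSE)
    isDup <- beaten
    free <- which(!beaten)
    if (length(free)) {
      fo <- free[order(fkey[free], -score[fragRows][free],
                       fragRows[free], method = "radix")]
      first <- !duplicated(fkey[fo])
      dupFree <- logical(length(fragRows))
      dupFree[fo] <- !first
      isDup <- isDup | dupFree
    }
    fragments$isDup <- isDup
  } else {
    fragments <- empty(lib = character(0), key = character(0),
                       qname = character(0), score = numeric(0),
                       row = integer(0), isDup = logical(0))
  }

  # --- rewrite flags on examined records only ---
  touched <- c(pairs$row1, pairs$row2, fragments$row)
  dupRows <- c(pairs$row1[pairs$isDup], pairs$row2[pairs$isDup],
               fragments$row[fragments$isDup])
  flag[touched] <- bitwAnd(flag[touched], bitwNot(0x400L))
  flag[dupRows] <- bitwOr(flag[dupRows], 0x400L)
  aln$flag <- flag
  sam@alignments <- aln
  list(sam = sam, pairs = pairs, fragments = fragments,
       pairEndKeys = pairEndKeys, warnings = warnings)
}

#' Parse flow-cell physical location from a read name
#'
#' Splits the qname on ":"; when there are at least 5 fields and the last
#' three parse as integers they are taken as (tile, x, y). Anything else
#' yields NA (never an error).
#'
#' @param qname character vector of read names.
#' @return data.frame with integer columns \code{tile}, \code{x}, \code{y}
#'   (all NA where the layout does not match).
#' @export
parsePhysicalLocation <- function(qname) {
  parts <- strsplit(qname, ":", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    if (length(p) < 5L) return(c(NA_integer_, NA_integer_, NA_integer_))
    last3 <- suppressWarnings(as.integer(tail(p, 3L)))
    if (anyNA(last3)) return(c(NA_integer_, NA_integer_, NA_integer_))
    last3
  }, integer(3)))
  data.frame(tile = out[, 1L], x = out[, 2L], y = out[, 3L])
}

#' Count optical duplicates within pair duplicate classes
#'
#' Two members of the same pair class are optically linked iff they come
#' from the same read group and tile and their x and y pixel offsets are
#' each at most \code{maxDistance} (per-axis rectangle test, Picard's
#' comparison; set \code{euclidean} for a radial test instead). Clusters
#' are the transitive closure of links. In a cluster containing the class
#' survivor every other member counts as optical; in survivor-free clusters
#' all but one count. Members without a parseable physical location are
#' never linked.
#'
#' @param dup result of [markDuplicates()].
#' @param maxDistance pixel threshold (default 100).
#' @param euclidean logical; use Euclidean distance instead of the
#'   per-axis test.
#' @return named numeric vector: optical pair-duplicate count per library.
#' @export
markOpticalDuplicates <- function(dup, maxDistance = 100L, euclidean = FALSE) {
  pairs <- dup$pairs
  libsAll <- unique(pairs$lib)
  counts <- setNames(numeric(length(libsAll)), libsAll)
  if (!nrow(pairs)) return(counts)
  loc <- parsePhysicalLocation(pairs$qname)
  for (k in unique(pairs$key[duplicated(pairs$key)])) {
    idx <- which(pairs$key == k)
    m <- length(idx)
    if (m < 2L) next
    tile <- loc$tile[idx]; x <- loc$x[idx]; y <- loc$y[idx]
    rgv <- pairs$rg[idx]
    parent <- seq_len(m)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(m - 1L)) {
      if (is.na(tile[i])) next
      for (j in (i + 1L):m) {
        if (is.na(tile[j]) || tile[i] != tile[j] || rgv[i] != rgv[j]) next
        linked <- if (euclidean)
          (x[i] - x[j])^2 + (y[i] - y[j])^2 <= maxDistance^2
        else
          abs(x[i] - x[j]) <= maxDistance && abs(y[i] - y[j]) <= maxDistance
        if (linked) {
          ri <- findRoot(i); rj <- findRoot(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    root <- vapply(seq_len(m), findRoot, integer(1))
    # every cluster contributes its size minus one: the survivor if the
    # cluster holds it, otherwise an arbitrary representative, is not optical
    for (cl in unique(root))
      counts[pairs$lib[idx][1L]] <-
        counts[pairs$lib[idx][1L]] + sum(root == cl) - 1L
  }
  counts
}

#' Estimate library size from duplication
#'
#' Solves the Lander-Waterman style saturation equation
#' \eqn{U = X (1 - e^{-N/X})} for the library size \eqn{X > 0}, where
#' \eqn{N} is the number of read pairs and \eqn{U} the number of distinct
#' pairs, by bisection to a relative tolerance of 1e-9. Returns NA when no
#' duplication was observed (U == N) or nothing was observed (U == 0),
#' where the equation has no informative root. Monotone: for fixed N the
#' estimate increases with U.
#'
#' @param nPairs total read pairs N.
#' @param uniquePairs distinct read pairs U (0 <= U <= N).
#' @return numeric library-size estimate, or NA.
#' @export
estimateLibrarySize <- function(nPairs, uniquePairs) {
  if (uniquePairs > nPairs) stop("uniquePairs must not exceed nPairs")
  if (uniquePairs == nPairs || uniquePairs == 0) return(NA_real_)
  f <- function(x) x * (1 - exp(-nPairs / x)) - uniquePairs
  lo <- uniquePairs / 2
  while (f(lo) > 0) lo <- lo / 2
  hi <- uniquePairs
  while (f(hi) < 0) hi <- hi * 2
  repeat {
    mid <- (lo + hi) / 2
    if ((hi - lo) / mid < 1e-9) return(mid)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
}
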