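# Base quality score recalibration: tabulation of empirical mismatch
# counts per covariate bin, hierarchical quality deltas, and application.
#
# Covariates are the GATK 4 standard set: read group, reported quality,
# machine cycle (signed; negated for second-of-pair reads) and preceding
# sequence context in sequencing orientation. Known polymorphic sites are
# masked so true variants are not counted as machine errors.

.revcompChar <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

.strrev <- function(x) {
  n <- nchar(x)
  if (!length(x)) return(x)
  if (max(n) <= 1L) return(x)
  if (max(n) == 2L) {
    two <- n == 2L
    x[two] <- paste0(substr(x[two], 2L, 2L), substr(x[two], 1L, 1L))
    return(x)
  }
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# expand eligible records into one row per base, with alignment info
# (refpos NA where the base is not aligned). usedRows: row indices of aln.
.expandBases <- function(aln, rows, aligned = TRUE) {
  if (!length(rows))
    return(data.table::data.table(rid = integer(0), qpos = integer(0),
                                  refpos = integer(0)))
  toks <- .cigarTokens(aln$cigar[rows])
  pieces <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    tk <- toks[[i]]
    qpos <- integer(0); refpos <- integer(0)
    q <- 1L; r <- aln$pos[rows[i]]
    for (j in seq_along(tk$op)) {
      len <- tk$len[j]; op <- tk$op[j]
      if (op %in% c("M", "=", "X")) {
        qpos <- c(qpos, q:(q + len - 1L))
        refpos <- c(refpos, r:(r + len - 1L))
        q <- q + len; r <- r + len
      } else if (op %in% c("I", "S")) {
        q <- q + len
      } else if (op %in% c("D", "N")) {
        r <- r + len
      } # H, P consume nothing
    }
    pieces[[i]] <- data.table::data.table(
      rid = rows[i], qpos = qpos, refpos = refpos)
  }
  data.table::rbindlist(pieces)
}

# per-base covariates for given (rid, qpos) rows; aln row-indexed by rid.
# Rows must be grouped contiguously by rid with qpos ascending within a
# group (both callers construct them that way).
.baseCovariates <- function(dt, aln, contextSize) {
  rid <- dt$rid
  L <- nchar(aln$seq)[rid]
  rev <- isReverse(aln$flag)[rid]
  second <- isPaired(aln$flag)[rid] & bitwAnd(aln$flag[rid], 0x80L) != 0L
  seqv <- aln$seq[rid]
  qpos <- dt$qpos
  dt$base <- toupper(substring(seqv, qpos, qpos))
  # qualities: decode each used record once, then index per group
  ids <- unique(rid)
  qualInt <- lapply(aln$qual[ids], function(qq)
    if (qq == "*") integer(0) else utf8ToInt(qq) - 33L)
  names(qualInt) <- as.character(ids)
  grp <- factor(rid, levels = ids)
  dt$q <- unlist(mapply(function(id, p) qualInt[[as.character(id)]][p],
                        ids, split(qpos, grp), SIMPLIFY = FALSE),
                 use.names = FALSE)
  cyc <- ifelse(rev, L - qpos + 1L, qpos)
  dt$cycle <- ifelse(second, -cyc, cyc)
  k <- contextSize
  ctxF <- substring(seqv, pmax(qpos - k, 1L), qpos - 1L)
  ctxR <- .strrev(.revcompChar(substring(seqv, qpos + 1L, pmin(qpos + k, L))))
  dt$context <- toupper(ifelse(rev, ctxR, ctxF))
  rgv <- getTagValue(aln$tags, "RG")[rid]
  dt$rg <- ifelse(is.na(rgv), "", rgv)
  dt
}

#' Tabulate recalibration statistics
#'
#' Counts observations and mismatches per covariate bin over every aligned
#' base (CIGAR M/=/X) of the usable records. A base contributes only when
#' its reference position is not masked by the known sites, and both the
#' read base and the reference base are unambiguous (A/C/G/T). Insertions,
#' deletions and clips contribute nothing. Records that are
#' duplicate-flagged, secondary, supplementary, unmapped or have mapping
#' quality 0 are skipped (so the input should already be duplicate-marked);
#' records with "*" quality strings are skipped when
#' \code{skipMissingQual} (the default policy).
#'
#' @param sam a [SamFile-class] (coordinate-sorted, duplicate-marked).
#' @param reference named character vector, contig -> sequence
#'   (see [readFastaRef()]).
#' @param known a [KnownSites-class] (may be empty).
#' @param contextSize number of preceding bases in the context covariate.
#' @param skipMissingQual skip records whose qual is "*" (otherwise error).
#' @param exclude character subset of
#'   c("duplicate","secondary","supplementary","unmapped","mapq0")
#'   controlling which records are skipped; the default mirrors GATK.
#' @return a [RecalTable-class] with counts (deltas not yet computed).
#' @export
bqsrTabulate <- function(sam, reference, known = NULL, contextSize = 2L,
                         skipMissingQual = TRUE,
                         exclude = c("duplicate", "secondary",
                                     "supplementary", "unmapped", "mapq0")) {
  aln <- sam@alignments
  flag <- aln$flag
  use <- rep(TRUE, nrow(aln))
  if ("unmapped" %in% exclude) use <- use & !isUnmapped(flag)
  use <- use & !isUnmapped(flag)   # unaligned records have no aligned bases
  if ("secondary" %in% exclude) use <- use & !isSecondary(flag)
  if ("supplementary" %in% exclude) use <- use & !isSupplementary(flag)
  if ("duplicate" %in% exclude) use <- use & !isDuplicate(flag)
  if ("mapq0" %in% exclude) use <- use & aln$mapq > 0L
  noQual <- aln$qual == "*" | aln$seq == "*"
  if (any(use & noQual)) {
    if (!skipMissingQual)
      stop("record with '*' quality string in recalibration tabulation")
    use <- use & !noQual
  }
  rows <- which(use)
  missingContig <- setdiff(unique(aln$rname[rows]), names(reference))
  if (length(missingContig))
    stop("contig missing from reference: ", missingContig[1L])
  dt <- .expandBases(aln, rows)
  if (nrow(dt)) {
    dt <- .baseCovariates(dt, aln, contextSize)
    # reference base per contig
    dt$refbase <- NA_character_
    contig <- aln$rname[dt$rid]
    for (ct in unique(contig)) {
      sel <- contig == ct
      dt$refbase[sel] <- substring(reference[[ct]], dt$refpos[sel], dt$refpos[sel])
    }
    # known-site masking
    if (!is.null(known)) {
      mask <- .sitesMask(known)
      if (length(mask)) {
        drop <- rep(FALSE, nrow(dt))
        for (ct in intersect(unique(contig), names(mask)))
          drop[contig == ct] <- dt$refpos[contig == ct] %in% mask[[ct]]
        dt <- dt[!drop, ]
      }
    }
    keepBase <- dt$base %in% c("A", "C", "G", "T") &
      dt$refbase %in% c("A", "C", "G", "T")
    dt <- dt[keepBase, ]
  }
  if (!nrow(dt)) {
    zero <- function(...) data.frame(...)
    return(new("RecalTable",
               global = zero(rg = character(0), obs = numeric(0),
                             err = numeric(0), sumQ = numeric(0)),
               byQ = zero(rg = character(0), q = integer(0),
                          obs = numeric(0), err = numeric(0)),
               byCycle = zero(rg = character(0), q = integer(0),
                              cycle = integer(0), obs = numeric(0),
                              err = numeric(0)),
               byContext = zero(rg = character(0), q = integer(0),
                                context = character(0), obs = numeric(0),
                                err = numeric(0)),
               params = list(context = as.integer(contextSize),
                             hasDeltas = FALSE)))
  }
  dt$err <- dt$base != dt$refbase
  dtt <- data.table::as.data.table(dt)
  # sumQ (exact integer sum of reported qualities) rather than the mean, so
  # that per-chunk tables reduce to bitwise the same global table
  g <- dtt[, list(obs = as.numeric(.N), err = as.numeric(sum(err)),
                  sumQ = as.numeric(sum(q))), by = "rg"]
  bq <- dtt[, list(obs = as.numeric(.N), err = as.numeric(sum(err))),
            by = c("rg", "q")]
  bc <- dtt[, list(obs = as.numeric(.N), err = as.numeric(sum(err))),
            by = c("rg", "q", "cycle")]
  bk <- dtt[, list(obs = as.numeric(.N), err = as.numeric(sum(err))),
            by = c("rg", "q", "context")]
  data.table::setorderv(g, "rg")
  data.table::setorderv(bq, c("rg", "q"))
  data.table::setorderv(bc, c("rg", "q", "cycle"))
  data.table::setorderv(bk, c("rg", "q", "context"))
  new("RecalTable",
      global = as.data.frame(g), byQ = as.data.frame(bq),
      byCycle = as.data.frame(bc), byContext = as.data.frame(bk),
      params = list(context = as.integer(contextSize), hasDeltas = FALSE))
}

#' Empirical quality of a covariate bin
#'
#' The maximum a posteriori Phred quality of a bin: the integer
#' \eqn{Q \in [0, 93]} maximizing the sum of a log-Gaussian prior centred
#' at \code{priorQ} with width \code{sigma} and the log-binomial likelihood
#' of \code{err} mismatches out of \code{obs} observations at error rate
#' \eqn{10^{-Q/10}}. With zero observations the prior centre is returned
#' unchanged. Likelihood ties resolve to the lowest Q.
#'
#' @param obs observation count.
#' @param err error (mismatch) count, <= obs.
#' @param priorQ prior centre (need not be an integer).
#' @param sigma Gaussian prior width on the Phred scale.
#' @return the empirical quality (integer-valued unless obs is 0).
#' @export
empiricalQuality <- function(obs, err, priorQ, sigma = 0.5) {
  stopifnot(obs >= err)
  if (obs == 0) return(priorQ)
  Qs <- 0:93
  ll <- dnorm(Qs, mean = priorQ, sd = sigma, log = TRUE) +
    dbinom(err, obs, 10^(-Qs / 10), log = TRUE)
  Qs[which.max(ll)]
}

#' Compute hierarchical quality deltas
#'
#' Fills in empirical qualities and deltas level by level: the global delta
#' per read group is the empirical quality of the whole read group minus
#' the count-weighted mean reported quality; the per-reported-quality delta
#' subtracts q and the global delta; cycle and context deltas subtract all
#' ancestors. Each level's empirical quality uses its parent's estimate as
#' the prior centre ([empiricalQuality()]). Deltas are stored rounded to 4
#' decimals, the precision of the on-disk report, so in-memory application
#' and write/read/apply agree exactly.
#'
#' @param table a [RecalTable-class] from [bqsrTabulate()].
#' @param sigma Gaussian prior width (Phred units).
#' @return the table with \code{empQ}/\code{delta} columns on every level.
#' @export
computeDeltas <- function(table, sigma = 0.5) {
  r4 <- function(x) round(x, 4L)
  g <- table@global
  if (nrow(g)) {
    estQ <- g$sumQ / g$obs
    g$empQ <- vapply(seq_len(nrow(g)), function(i)
      empiricalQuality(g$obs[i], g$err[i], estQ[i], sigma), numeric(1))
    g$delta <- r4(g$empQ - estQ)
    g$estQ <- r4(estQ)
  } else { g$empQ <- numeric(0); g$delta <- numeric(0); g$estQ <- numeric(0) }
  dG <- setNames(g$delta, g$rg)

  bq <- table@byQ
  if (nrow(bq)) {
    prior <- bq$q + dG[bq$rg]
    bq$empQ <- vapply(seq_len(nrow(bq)), function(i)
      empiricalQuality(bq$obs[i], bq$err[i], prior[i], sigma), numeric(1))
    bq$delta <- r4(bq$empQ - bq$q - dG[bq$rg])
  } else { bq$empQ <- numeric(0); bq$delta <- numeric(0) }
  dR <- setNames(bq$delta, paste(bq$rg, bq$q, sep = "\r"))

  subDelta <- function(df) {
    if (!nrow(df)) { df$empQ <- numeric(0); df$delta <- numeric(0); return(df) }
    parent <- df$q + dG[df$rg] + dR[paste(df$rg, df$q, sep = "\r")]
    df$empQ <- vapply(seq_len(nrow(df)), function(i)
      empiricalQuality(df$obs[i], df$err[i], parent[i], sigma), numeric(1))
    df$delta <- r4(df$empQ - parent)
    df
  }
  new("RecalTable", global = g, byQ = bq,
      byCycle = subDelta(table@byCycle),
      byContext = subDelta(table@byContext),
      params = list(context = table@params$context, hasDeltas = TRUE,
                    sigma = sigma))
}

#' Merge recalibration tables
#'
#' Sums observation/error counts of tables tabulated over disjoint record
#' sets (the reduce step of the split-filter-merge mode). Count-weighted
#' mean reported qualities are recombined accordingly. Deltas, if any, are
#' dropped; call [computeDeltas()] on the merged result.
#'
#' @param tables list of [RecalTable-class] objects with identical
#'   covariate configuration.
#' @return the merged counts-only [RecalTable-class].
#' @export
mergeRecalTables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  k <- unique(vapply(tables, function(t) t@params$context, integer(1)))
  if (length(k) != 1L) stop("tables have differing context sizes")
  sumUp <- function(slot, keys) {
    dfs <- lapply(tables, function(t) {
      d <- methods::slot(t, slot)
      d[c(keys, "obs", "err", if (slot == "global") "sumQ")]
    })
    dt <- data.table::rbindlist(dfs)
    if (!nrow(dt)) return(as.data.frame(dfs[[1L]]))
    if (slot == "global") {
      out <- dt[, list(obs = sum(obs), err = sum(err), sumQ = sum(sumQ)),
                by = keys]
    } else {
      out <- dt[, list(obs = sum(obs), err = sum(err)), by = keys]
    }
    data.table::setorderv(out, keys)
    as.data.frame(out)
  }
  new("RecalTable",
      global = sumUp("global", "rg"),
      byQ = sumUp("byQ", c("rg", "q")),
      byCycle = sumUp("byCycle", c("rg", "q", "cycle")),
      byContext = sumUp("byContext", c("rg", "q", "context")),
      params = list(context = k, hasDeltas = FALSE))
}

#' Learn quality quantization levels
#'
#' Deterministic one-dimensional k-means (Lloyd iterations from
#' evenly-spaced quantile seeds) over the observed recalibrated qualities,
#' used to compress the quality distribution to a fixed number of levels.
#'
#' @param quals integer vector of qualities (one entry per base, or use
#'   \code{weights}).
#' @param nLevels number of levels to learn.
#' @param weights optional per-entry weights.
#' @return sorted integer vector of levels.
#' @export
learnQuantizationLevels <- function(quals, nLevels, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(quals))
  u <- sort(unique(quals))
  if (length(u) <= nLevels) return(u)
  w <- vapply(u, function(v) sum(weights[quals == v]), numeric(1))
  centers <- stats::quantile(rep(u, times = round(w / min(w))),
                             probs = seq(0, 1, length.out = nLevels),
                             names = FALSE, type = 1)
  centers <- sort(unique(centers))
  repeat {
    assign <- vapply(u, function(v) which.min(abs(v - centers)), integer(1))
    newc <- vapply(seq_along(centers), function(i) {
      sel <- assign == i
      if (!any(sel)) centers[i] else sum(u[sel] * w[sel]) / sum(w[sel])
    }, numeric(1))
    if (max(abs(newc - centers)) < 1e-9) break
    centers <- newc
  }
  sort(unique(as.integer(round(centers))))
}

#' Apply base quality score recalibration
#'
#' Rewrites the QUAL string of every record (including duplicates and
#' unmapped reads -- the tabulation exclusions do not apply here): each
#' base with reported quality >= \code{preserveBelow} gets
#' round(q + global + reported + cycle + context deltas), clamped to
#' [1, 93], then optionally snapped to the nearest quantization level.
#' Bases whose covariate bin is missing from the table fall back to the
#' deltas of the deepest available ancestor bin; reads from a read group
#' absent from the table are left unchanged. Only QUAL changes. Records
#' with "*" qualities are left untouched.
#'
#' @param sam a [SamFile-class].
#' @param table a [RecalTable-class] with deltas ([computeDeltas()]).
#' @param quantizeLevels NULL, or an integer number of levels to learn
#'   ([learnQuantizationLevels()]), or an explicit integer vector of
#'   levels.
#' @param preserveBelow qualities below this are passed through unchanged.
#' @return the [SamFile-class] with recalibrated QUAL strings.
#' @export
applyBqsr <- function(sam, table, quantizeLevels = NULL, preserveBelow = 6L) {
  if (!isTRUE(table@params$hasDeltas))
    stop("table has no deltas; run computeDeltas() first")
  aln <- sam@alignments
  rows <- which(aln$qual != "*" & aln$seq != "*")
  if (!length(rows) || !nrow(table@global)) return(sam)
  L <- nchar(aln$seq[rows])
  dt <- data.table::data.table(
    rid = rep(rows, L),
    qpos = unlist(lapply(L, seq_len)))
  dt <- .baseCovariates(dt, aln, table@params$context)
  dG <- setNames(table@global$delta, table@global$rg)
  kQ <- paste(table@byQ$rg, table@byQ$q, sep = "\r")
  dR <- setNames(table@byQ$delta, kQ)
  dC <- setNames(table@byCycle$delta,
                 paste(table@byCycle$rg, table@byCycle$q,
                       table@byCycle$cycle, sep = "\r"))
  dK <- setNames(table@byContext$delta,
                 paste(table@byContext$rg, table@byContext$q,
                       table@byContext$context, sep = "\r"))
  q <- dt$q
  add <- dG[dt$rg]
  known <- !is.na(add)                       # read group present in table
  kq <- paste(dt$rg, q, sep = "\r")
  add <- add + ifelse(is.na(dR[kq]), 0, dR[kq])
  add <- add + ifelse(is.na(dC[paste(dt$rg, q, dt$cycle, sep = "\r")]), 0,
                      dC[paste(dt$rg, q, dt$cycle, sep = "\r")])
  add <- add + ifelse(is.na(dK[paste(dt$rg, q, dt$context, sep = "\r")]), 0,
                      dK[paste(dt$rg, q, dt$context, sep = "\r")])
  newQ <- q
  recal <- known & q >= preserveBelow
  newQ[recal] <- pmin(pmax(floor(q[recal] + add[recal] + 0.5), 1L), 93L)
  if (!is.null(quantizeLevels)) {
    levels <- if (length(quantizeLevels) == 1L)
      learnQuantizationLevels(newQ[recal], quantizeLevels) else
      sort(as.integer(quantizeLevels))
    snap <- function(v) levels[max.col(-abs(outer(v, levels, "-")),
                                       ties.method = "first")]
    if (any(recal)) newQ[recal] <- snap(newQ[recal])
  }
  # reassemble per record
  newQ <- as.integer(newQ)
  byRec <- split(newQ, dt$rid)
  qualNew <- vapply(byRec, function(v) intToUtf8(v + 33L), character(1))
  aln$qual[as.integer(names(byRec))] <- unname(qualNew)
  sam@alignments <- aln
  sam
}
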