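# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive everything from first principles (explicit CIGAR
# walks, exhaustive pairwise comparison, all-pairs transitive closure)
# rather than calling into the engine's vectorized paths.

# ---- fixture builders ----

mkRecord <- function(qname = "r", flag = 0L, rname = "chr1", pos = 100L,
                     mapq = 60L, cigar = "10M", rnext = "*", pnext = 0L,
                     tlen = 0L, seq = NULL, qual = NULL, tags = "") {
  n <- oracleCigarQueryLen(cigar)
  if (is.null(seq)) seq <- if (n > 0L) strrep("A", n) else "*"
  if (is.null(qual)) qual <- if (n > 0L) strrep("I", n) else "*"
  list(qname = qname, flag = flag, rname = rname, pos = pos, mapq = mapq,
       cigar = cigar, rnext = rnext, pnext = pnext, tlen = tlen,
       seq = seq, qual = qual, tags = tags)
}

mkSam <- function(records, sq = c(chr1 = 10000L, chr2 = 8000L),
                  rg = data.frame(ID = "rg1", LB = "lib1", PU = "run1")) {
  hdr <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:", names(sq), "\tLN:", unname(sq)),
           paste0("@RG\tID:", rg$ID, "\tLB:", rg$LB, "\tPU:", rg$PU))
  body <- vapply(records, function(r) {
    line <- paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
                  r$rnext, r$pnext, r$tlen, r$seq, r$qual, sep = "\t")
    if (nzchar(r$tags)) paste(line, r$tags, sep = "\t") else line
  }, character(1))
  readSam(samText(c(hdr, body)))
}

phredStr <- function(q) intToUtf8(q + 33L)

# identical-key read pairs differing only in qname (flow-cell coordinates),
# for optical-clustering cases
mkPairRecs <- function(qnames, pos1 = 100L, quals = NULL) {
  unlist(lapply(seq_along(qnames), function(i) {
    q <- if (is.null(quals)) phredStr(rep(30L, 10L)) else quals[[i]]
    list(mkRecord(qname = qnames[i], flag = bitwOr(0x1L, 0x20L), pos = pos1,
                  cigar = "10M", rnext = "=", pnext = pos1 + 50L, qual = q,
                  tags = "RG:Z:rg1"),
         mkRecord(qname = qnames[i], flag = bitwOr(0x1L, bitwOr(0x10L, 0x80L)),
                  pos = pos1 + 50L, cigar = "10M", rnext = "=", pnext = pos1,
                  qual = q, tags = "RG:Z:rg1"))
  }), recursive = FALSE)
}

# ---- oracle CIGAR arithmetic (explicit token scan) ----

oracleCigarTokens <- function(cigar) {
  if (cigar == "*") return(list())
  out <- list()
  num <- ""
  for (ch in strsplit(cigar, "")[[1L]]) {
    if (ch >= "0" && ch <= "9") num <- paste0(num, ch)
    else { out[[length(out) + 1L]] <- list(len = as.integer(num), op = ch)
           num <- "" }
  }
  out
}

oracleCigarQueryLen <- function(cigar) {
  sum(vapply(oracleCigarTokens(cigar), function(t)
    if (t$op %in% c("M", "I", "S", "=", "X")) t$len else 0L, integer(1)))
}

oracleRefLen <- function(cigar) {
  sum(vapply(oracleCigarTokens(cigar), function(t)
    if (t$op %in% c("M", "D", "N", "=", "X")) t$len else 0L, integer(1)))
}

oracleUnclipped <- function(pos, cigar, reverse) {
  toks <- oracleCigarTokens(cigar)
  ops <- vapply(toks, `[[`, character(1), "op")
  lens <- vapply(toks, `[[`, integer(1), "len")
  body <- which(!(ops %in% c("S", "H")))
  lead <- if (length(body)) sum(lens[seq_len(min(body) - 1L)]) else sum(lens)
  trail <- if (length(body) && max(body) < length(ops))
    sum(lens[(max(body) + 1L):length(ops)]) else 0L
  if (reverse) pos + oracleRefLen(cigar) - 1L + trail else pos - lead
}

oracleScore <- function(qual) {
  if (qual == "*") return(0)
  v <- utf8ToInt(qual) - 33L
  sum(v[v >= 15L])
}

# ---- exhaustive pairwise duplicate classifier ----
# Returns the expected duplicate flag (logical) per record, given the
# record order of `aln` as the tie-break order.
oracleMarkDuplicates <- function(sam) {
  aln <- alignments(sam)
  hdrLibs <- rgLibraries(samHeader(sam))
  n <- nrow(aln)
  fl <- aln$flag
  bit <- function(f, b) bitwAnd(f, b) != 0L
  eligible <- !bit(fl, 0x4) & !bit(fl, 0x100) & !bit(fl, 0x800)
  lib <- vapply(seq_len(n), function(i) {
    rg <- getTagValue(aln$tags[i], "RG")
    l <- if (is.na(rg)) NA_character_ else hdrLibs[[rg]]
    if (is.na(l) || is.null(l)) "Unknown Library" else l
  }, character(1))
  ucp <- vapply(seq_len(n), function(i)
    if (bit(fl[i], 0x4)) NA_integer_
    else oracleUnclipped(aln$pos[i], aln$cigar[i], bit(fl[i], 0x10)),
    integer(1))
  strand <- ifelse(bit(fl, 0x10), "R", "F")
  score <- vapply(aln$qual, oracleScore, numeric(1), USE.NAMES = FALSE)

  pairCand <- which(eligible & bit(fl, 0x1) & !bit(fl, 0x8))
  tab <- table(aln$qname[pairCand])
  pairQ <- names(tab)[tab == 2L]
  pairRows <- lapply(pairQ, function(q) sort(pairCand[aln$qname[pairCand] == q]))
  endOf <- function(r) list(ct = aln$rname[r], u = ucp[r], s = strand[r])
  endEq <- function(a, b) a$ct == b$ct && a$u == b$u && a$s == b$s
  pairEq <- function(i, j) {
    pi <- pairRows[[i]]; pj <- pairRows[[j]]
    if (lib[pi[1L]] != lib[pj[1L]]) return(FALSE)
    a1 <- endOf(pi[1L]); a2 <- endOf(pi[2L])
    b1 <- endOf(pj[1L]); b2 <- endOf(pj[2L])
    (endEq(a1, b1) && endEq(a2, b2)) || (endEq(a1, b2) && endEq(a2, b1))
  }
  nP <- length(pairRows)
  dupFlag <- rep(NA, n)            # NA = untouched
  dupFlag[unlist(pairRows)] <- FALSE
  if (nP) {
    cls <- seq_len(nP)
    for (i in seq_len(nP - 1L)) for (j in (i + 1L):nP)
      if (cls[j] > cls[i] && pairEq(i, j)) cls[cls == cls[j]] <- cls[i]
    for (c0 in unique(cls)) {
      members <- which(cls == c0)
      if (length(members) < 2L) next
      sc <- vapply(members, function(m) sum(score[pairRows[[m]]]), numeric(1))
      idx <- vapply(members, function(m) min(pairRows[[m]]), numeric(1))
      best <- members[order(-sc, idx)][1L]
      for (m in setdiff(members, best))
        dupFlag[pairRows[[m]]] <- TRUE
    }
  }
  fragRows <- setdiff(which(eligible & !bit(fl, 0x4)), unlist(pairRows))
  dupFlag[fragRows] <- FALSE
  if (length(fragRows)) {
    fragKey <- function(r) paste(lib[r], aln$rname[r], ucp[r], strand[r])
    pairEnds <- unlist(lapply(pairRows, function(p)
      c(fragKey(p[1L]), fragKey(p[2L]))))
    keys <- vapply(fragRows, fragKey, character(1))
    beaten <- keys %in% pairEnds
    dupFlag[fragRows[beaten]] <- TRUE
    for (k in unique(keys[!beaten])) {
      members <- fragRows[!beaten & keys == k]
      if (length(members) < 2L) next
      best <- members[order(-score[members], members)][1L]
      dupFlag[setdiff(members, best)] <- TRUE
    }
  }
  dupFlag
}

# ---- all-pairs transitive closure for optical clustering ----
# locs: data.frame(tile, x, y, rg, lib, isSurvivor) of one duplicate class.
# Returns the optical count for the class.
oracleOpticalCount <- function(locs, maxDistance) {
  m <- nrow(locs)
  if (m < 2L) return(0L)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    if (is.na(locs$tile[i]) || is.na(locs$tile[j])) next
    adj[i, j] <- locs$tile[i] == locs$tile[j] && locs$rg[i] == locs$rg[j] &&
      abs(locs$x[i] - locs$x[j]) <= maxDistance &&
      abs(locs$y[i] - locs$y[j]) <= maxDistance
  }
  reach <- adj | diag(m)
  repeat {                         # transitive closure by squaring
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, m)
  c0 <- 0L
  for (i in seq_len(m)) if (is.na(comp[i])) {
    c0 <- c0 + 1L
    comp[which(reach[i, ])] <- c0
  }
  sum(table(comp) - 1L)
}

# ---- brute-force region membership (per-base scan of raw BED lines) ----
oracleBedOverlap <- function(bedLines, contig, refPositions) {
  if (!length(refPositions)) return(FALSE)
  for (ln in bedLines) {
    f <- strsplit(ln, "\t")[[1L]]
    if (f[1L] != contig) next
    lo <- as.integer(f[2L]) + 1L; hi <- as.integer(f[3L])
    if (any(refPositions >= lo & refPositions <= hi)) return(TRUE)
  }
  FALSE
}

# reference positions covered by an alignment (M/D/N/=/X)
oracleRefPositions <- function(pos, cigar) {
  p <- pos
  out <- integer(0)
  for (t in oracleCigarTokens(cigar)) {
    if (t$op %in% c("M", "D", "N", "=", "X")) {
      out <- c(out, p:(p + t$len - 1L)); p <- p + t$len
    }
  }
  out
}

# random small SAM files for oracle comparisons
randomSamFile <- function(seed, nRecords = 80L) {
  set.seed(seed)
  sq <- c(chrA = 5000L, chrB = 4000L)
  rg <- data.frame(ID = c("rgX", "rgY"), LB = c("L1", "L2"),
                   PU = c("u1", "u1"))
  recs <- list()
  i <- 0L
  while (length(recs) < nRecords) {
    i <- i + 1L
    kind <- sample(c("pair", "frag", "unmapped", "secondary"), 1L,
                   prob = c(0.5, 0.3, 0.1, 0.1))
    rgid <- sample(rg$ID, 1L)
    tag <- paste0("RG:Z:", rgid)
    qn <- sprintf("q%03d:%d:%d:%d", i, sample(4, 1), sample(300, 1),
                  sample(300, 1))
    ct <- sample(names(sq), 1L)
    # deliberately small position range to force key collisions
    p <- sample(30:80, 1L)
    readLen <- 20L
    mkq <- function() phredStr(sample(c(2L, 10L, 20L, 30L), readLen,
                                      replace = TRUE))
    clip <- function() sample(0:3, 1L)
    cigarFor <- function(c1, rev) {
      body <- readLen - c1
      if (c1 == 0L) paste0(body + c1, "M")
      else if (rev) sprintf("%dM%dS", body, c1) else sprintf("%dS%dM", body, c1)
    }
    if (kind == "pair") {
      rev2 <- TRUE; rev1 <- FALSE
      c1 <- clip(); c2 <- clip()
      p2 <- p + sample(25:60, 1L)
      recs[[length(recs) + 1L]] <- mkRecord(
        qname = qn, flag = bitwOr(0x1L, bitwOr(0x40L, 0x20L)),
        rname = ct, pos = p + c1, cigar = cigarFor(c1, FALSE),
        rnext = "=", pnext = p2, qual = mkq(), tags = tag)
      recs[[length(recs) + 1L]] <- mkRecord(
        qname = qn, flag = bitwOr(0x1L, bitwOr(0x80L, 0x10L)),
        rname = ct, pos = p2, cigar = cigarFor(c2, TRUE),
        rnext = "=", pnext = p + c1, qual = mkq(), tags = tag)
    } else if (kind == "frag") {
      rev <- runif(1) < 0.5
      c1 <- clip()
      recs[[length(recs) + 1L]] <- mkRecord(
        qname = qn, flag = if (rev) 0x10L else 0L, rname = ct,
        pos = if (rev) p else p + c1, cigar = cigarFor(c1, rev),
        qual = mkq(), tags = tag)
    } else if (kind == "unmapped") {
      recs[[length(recs) + 1L]] <- mkRecord(
        qname = qn, flag = 0x4L, rname = "*", pos = 0L, mapq = 0L,
        cigar = "*", seq = strrep("A", readLen), qual = mkq(), tags = tag)
    } else {
      recs[[length(recs) + 1L]] <- mkRecord(
        qname = qn, flag = bitwOr(0x100L, if (runif(1) < .5) 0x10L else 0L),
        rname = ct, pos = p, cigar = paste0(readLen, "M"),
        qual = mkq(), tags = tag)
    }
  }
  mkSam(recs, sq = sq, rg = rg)
}
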