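# Seeded synthetic fixture generator. Emits pre-aligned reads (consistent
# POS/CIGAR written directly; alignment itself is out of scope) together
# with ground-truth tables computed in "generator space" -- from the
# planted origins, scores and coordinates, not from the CIGAR/flag
# machinery the package itself uses -- so they can serve as independent
# oracles for duplicate marking, optical clustering and recalibration.

BASES <- c("A", "C", "G", "T")

#' Generate a random reference genome
#'
#' Reproducible uniform A/C/G/T sequences.
#'
#' @param contigs named integer vector: contig name -> length.
#' @param seed RNG seed.
#' @param fasta optional path; when given the reference is also written as
#'   FASTA (60-column lines).
#' @return named character vector (contig -> sequence).
#' @export
simReference <- function(contigs = c(chr1 = 12000L, chr2 = 9000L, chr3 = 7000L),
                         seed = 1L, fasta = NULL) {
  stopifnot(all(contigs > 0))
  set.seed(seed)
  ref <- vapply(contigs, function(L)
    paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1))
  if (!is.null(fasta)) {
    dss <- Biostrings::DNAStringSet(ref)
    names(dss) <- names(ref)
    Biostrings::writeXStringSet(dss, fasta, width = 60L)
  }
  ref
}

.randSeq <- function(n) if (n > 0L)
  paste(sample(BASES, n, replace = TRUE), collapse = "") else ""

# sample from the values of x (never the 1:x trap for scalar numeric x)
.sampleFrom <- function(x, n, replace = TRUE)
  x[sample.int(length(x), n, replace = replace)]

.otherBase <- function(b) {
  alt <- setdiff(BASES, b)
  alt[sample.int(3L, 1L)]
}

#' Generate synthetic aligned reads with ground truth
#'
#' Emits a read set exercising every stage of the preparation pipeline:
#' mapped pairs (a configurable fraction spanning two contigs), planted
#' PCR-duplicate groups whose members share unclipped keys but differ in
#' soft clipping and base qualities, flow-cell coordinates planted in the
#' read names with controlled pixel offsets, unpaired fragments (some
#' colliding with pair ends to exercise the pairs-beat-fragments rule),
#' mate-unmapped pairs, unmapped and secondary records, sequencing errors
#' injected at per-quality rates of 10^(-q/10) with an optional per-cycle
#' boost, and known polymorphic sites (SNPs plus a fraction of 2-base
#' deletion alleles) at which reads carry the alternate allele.
#'
#' Truth tables are computed from the planted quantities and account for
#' accidental key collisions between independently placed reads (grouping
#' is over the planted keys themselves):
#' \itemize{
#'  \item \code{reads}: per mapped primary read its true library, unclipped
#'    key, score and duplicate status (ties broken by final file order);
#'  \item \code{opticalTruth}: per-library optical duplicate count from a
#'    transitive closure over the planted tile/x/y coordinates;
#'  \item \code{baseCounts}: per (read group, reported quality, signed
#'    cycle) aligned-base and planted-error tallies over
#'    tabulation-eligible reads with full-span known-site masking applied;
#'  \item \code{maskedObs}: number of eligible aligned bases removed by
#'    that masking;
#'  \item \code{sites}/\code{vcf}: the planted known sites and their VCF.
#' }
#'
#' @param reference named character vector from [simReference()].
#' @param nPairs number of distinct pair origins.
#' @param readLen read length (bases).
#' @param fragmentRange min/max outer fragment length.
#' @param readGroups data.frame with columns ID, LB, PU.
#' @param dupProfile list(nGroups, sizeRange, clipMax): the first nGroups
#'   origins receive extra pair copies (PCR duplicates).
#' @param fracUnpaired,fracCollision unpaired fragments per pair origin,
#'   and the fraction of them planted exactly on a pair end key.
#' @param fracCrossContig fraction of pairs whose mate maps to another
#'   contig.
#' @param fracMateUnmapped fraction of pairs with an unmapped mate.
#' @param fracUnmappedSingles,fracSecondary,fracMapq0 rates of unmapped
#'   singleton records, secondary copies, and mapping-quality-0 reads.
#' @param errorProfile list(qualities, boostCycles, boostFactor): reported
#'   qualities are drawn uniformly from \code{qualities}; a base of
#'   quality q mismatches with probability 10^(-q/10), multiplied by
#'   \code{boostFactor} on the \code{boostCycles}.
#' @param knownSitesProfile list(n, altFraction, fracSpan2).
#' @param opticalProfile list(tiles, width, nearOffset, chainProb,
#'   maxDistance): duplicate-group members chain within nearOffset pixels
#'   of the previous member with probability chainProb, else land at a
#'   fresh random location.
#' @param seed RNG seed.
#' @return list: \code{sam} ([SamFile-class]), \code{reads},
#'   \code{opticalTruth}, \code{baseCounts}, \code{maskedObs},
#'   \code{errors}, \code{sites}, \code{vcf} (character lines).
#' @export
simReads <- function(reference,
                     nPairs = 300L, readLen = 100L,
                     fragmentRange = c(180L, 320L),
                     readGroups = data.frame(
                       ID = c("rg1", "rg2"), LB = c("libA", "libB"),
                       PU = c("run1", "run1"), stringsAsFactors = FALSE),
                     dupProfile = list(nGroups = 15L, sizeRange = c(2L, 4L),
                                       clipMax = 4L),
                     fracUnpaired = 0.12, fracCollision = 0.25,
                     fracCrossContig = 0.05, fracMateUnmapped = 0.03,
                     fracUnmappedSingles = 0.04, fracSecondary = 0.02,
                     fracMapq0 = 0.02,
                     errorProfile = list(qualities = c(20L, 25L, 30L, 35L),
                                         boostCycles = integer(0),
                                         boostFactor = 10),
                     knownSitesProfile = list(n = 40L, altFraction = 0.5,
                                              fracSpan2 = 0.25),
                     opticalProfile = list(tiles = 4L, width = 20000L,
                                           nearOffset = 40L, chainProb = 0.5,
                                           maxDistance = 100L),
                     seed = 1L) {
  stopifnot(readLen <= min(nchar(reference)))
  rates <- 10^(-errorProfile$qualities / 10)
  if (any(rates * errorProfile$boostFactor > 1))
    stop("infeasible error profile: boosted rate exceeds 1")
  set.seed(seed)
  contigs <- names(reference)
  clen <- nchar(reference)
  op <- opticalProfile

  # ---- known sites ----
  nSites <- knownSitesProfile$n
  if (nSites > 0L) {
    sct <- sample(contigs, nSites, replace = TRUE, prob = clen)
    spos <- vapply(sct, function(ct)
      sample.int(clen[[ct]] - readLen * 2L, 1L) + readLen, integer(1))
    span <- ifelse(runif(nSites) < knownSitesProfile$fracSpan2, 2L, 1L)
    sites <- data.frame(contig = unname(sct), pos = unname(spos),
                        span = span, stringsAsFactors = FALSE)
    sites <- sites[order(sites$contig, sites$pos, method = "radix"), ]
    sites <- sites[!duplicated(sites[c("contig", "pos")]), ]
    rownames(sites) <- NULL
    # the base carrying the alternate allele: the site position for SNPs,
    # the base after it for deletion-allele sites (which is masked only
    # under full-span masking)
    sites$altPos <- sites$pos + sites$span - 1L
    sites$altBase <- vapply(seq_len(nrow(sites)), function(i)
      .otherBase(substr(reference[[sites$contig[i]]], sites$altPos[i],
                        sites$altPos[i])), character(1))
  } else {
    sites <- data.frame(contig = character(0), pos = integer(0),
                        span = integer(0), altPos = integer(0),
                        altBase = character(0), stringsAsFactors = FALSE)
  }
  altAt <- setNames(sites$altBase, paste(sites$contig, sites$altPos))
  maskFull <- if (nrow(sites)) split(
    unlist(lapply(seq_len(nrow(sites)), function(i)
      sites$pos[i]:(sites$pos[i] + sites$span[i] - 1L))),
    rep(sites$contig, sites$span)) else list()

  # ---- pair plan ----
  nGroups <- min(dupProfile$nGroups, nPairs)
  copies <- rep(1L, nPairs)
  if (nGroups > 0L)
    copies[seq_len(nGroups)] <- .sampleFrom(
      dupProfile$sizeRange[1L]:dupProfile$sizeRange[2L], nGroups)
  originCt <- sample(contigs, nPairs, replace = TRUE, prob = clen)
  fragLen <- .sampleFrom(fragmentRange[1L]:fragmentRange[2L], nPairs)
  leftPos <- vapply(seq_len(nPairs), function(i)
    sample.int(clen[[originCt[i]]] - fragLen[i], 1L), integer(1))
  crossing <- runif(nPairs) < fracCrossContig & length(contigs) > 1L
  mateCt <- originCt
  matePos <- integer(nPairs)
  for (i in which(crossing)) {
    mateCt[i] <- sample(setdiff(contigs, originCt[i]), 1L)
    matePos[i] <- sample.int(clen[[mateCt[i]]] - readLen, 1L)
  }
  mateUnmapped <- !crossing & runif(nPairs) < fracMateUnmapped
  rgIdx <- sample.int(nrow(readGroups), nPairs, replace = TRUE)

  # ---- expand into per-read metadata rows (generator space) ----
  rows <- list()
  serial <- 0L
  addRow <- function(...) rows[[length(rows) + 1L]] <<- list(...)
  for (i in seq_len(nPairs)) {
    grpId <- if (i <= nGroups) i else NA_integer_
    e1 <- list(ct = originCt[i], u = leftPos[i], s = "F")
    e2 <- if (crossing[i])
      list(ct = mateCt[i], u = matePos[i] + readLen - 1L, s = "R")
    else
      list(ct = originCt[i], u = leftPos[i] + fragLen[i] - 1L, s = "R")
    prevLoc <- NULL
    for (cp in seq_len(copies[i])) {
      serial <- serial + 1L
      if (is.null(prevLoc) || runif(1) >= op$chainProb) {
        loc <- c(tile = sample.int(op$tiles, 1L),
                 x = sample.int(op$width, 1L), y = sample.int(op$width, 1L))
      } else {
        loc <- c(tile = prevLoc[["tile"]],
                 x = max(1L, prevLoc[["x"]] +
                           sample(seq.int(-op$nearOffset, op$nearOffset), 1L)),
                 y = max(1L, prevLoc[["y"]] +
                           sample(seq.int(-op$nearOffset, op$nearOffset), 1L)))
      }
      prevLoc <- loc
      qn <- sprintf("SIM:%d:FC:1:%d:%d:%d", serial,
                    loc[["tile"]], loc[["x"]], loc[["y"]])
      rg <- readGroups$ID[rgIdx[i]]
      if (mateUnmapped[i]) {
        addRow(qname = qn, kind = "pairFrag", pairId = i, grp = grpId,
               mate = 1L, rg = rg, ct = e1$ct, u = e1$u, s = e1$s,
               tile = loc[["tile"]], x = loc[["x"]], y = loc[["y"]])
        addRow(qname = qn, kind = "unmappedMate", pairId = i, grp = grpId,
               mate = 2L, rg = rg, ct = NA_character_, u = NA_integer_,
               s = NA_character_, tile = loc[["tile"]], x = loc[["x"]],
               y = loc[["y"]])
      } else {
        firstIsFwd <- runif(1) < 0.5
        addRow(qname = qn, kind = "pair", pairId = i, grp = grpId,
               mate = if (firstIsFwd) 1L else 2L, rg = rg,
               ct = e1$ct, u = e1$u, s = e1$s,
               tile = loc[["tile"]], x = loc[["x"]], y = loc[["y"]])
        addRow(qname = qn, kind = "pair", pairId = i, grp = grpId,
               mate = if (firstIsFwd) 2L else 1L, rg = rg,
               ct = e2$ct, u = e2$u, s = e2$s,
               tile = loc[["tile"]], x = loc[["x"]], y = loc[["y"]])
      }
    }
  }
  nFrag <- round(fracUnpaired * nPairs)
  for (j in seq_len(nFrag)) {
    serial <- serial + 1L
    qn <- sprintf("SIMF:%d:FC:1:%d:%d:%d", serial,
                  sample.int(op$tiles, 1L), sample.int(op$width, 1L),
                  sample.int(op$width, 1L))
    if (runif(1) < fracCollision) {
      i <- sample.int(nPairs, 1L)
      onRight <- !mateUnmapped[i] && !crossing[i] && runif(1) < 0.5
      addRow(qname = qn, kind = "frag", pairId = NA_integer_,
             grp = NA_integer_, mate = 0L, rg = readGroups$ID[rgIdx[i]],
             ct = originCt[i],
             u = if (onRight) leftPos[i] + fragLen[i] - 1L else leftPos[i],
             s = if (onRight) "R" else "F",
             tile = NA_integer_, x = NA_integer_, y = NA_integer_)
    } else {
      ct <- sample(contigs, 1L, prob = clen)
      s <- sample(c("F", "R"), 1L)
      base <- sample.int(clen[[ct]] - readLen, 1L)
      addRow(qname = qn, kind = "frag", pairId = NA_integer_,
             grp = NA_integer_, mate = 0L,
             rg = readGroups$ID[sample.int(nrow(readGroups), 1L)],
             ct = ct, u = if (s == "F") base else base + readLen - 1L, s = s,
             tile = NA_integer_, x = NA_integer_, y = NA_integer_)
    }
  }
  for (j in seq_len(round(fracUnmappedSingles * nPairs))) {
    serial <- serial + 1L
    addRow(qname = sprintf("SIMU:%d", serial), kind = "unmapped",
           pairId = NA_integer_, grp = NA_integer_, mate = 0L,
           rg = readGroups$ID[sample.int(nrow(readGroups), 1L)],
           ct = NA_character_, u = NA_integer_, s = NA_character_,
           tile = NA_integer_, x = NA_integer_, y = NA_integer_)
  }

  meta <- as.data.frame(data.table::rbindlist(rows))
  n <- nrow(meta)
  meta$mapq <- ifelse(meta$kind %in% c("unmapped", "unmappedMate"), 0L, 60L)
  mappedIdx <- which(!meta$kind %in% c("unmapped", "unmappedMate"))
  nM0 <- round(fracMapq0 * length(mappedIdx))
  if (nM0 > 0L) meta$mapq[.sampleFrom(mappedIdx, nM0, replace = FALSE)] <- 0L
  meta$clip <- 0L
  meta$clip[mappedIdx] <- .sampleFrom(0L:dupProfile$clipMax, length(mappedIdx))

  # ---- materialize sequences, qualities and planted errors ----
  qualSet <- errorProfile$qualities
  boostC <- errorProfile$boostCycles
  boostF <- errorProfile$boostFactor
  seqs <- character(n); quals <- character(n)
  pos <- integer(n); cig <- character(n)
  qList <- vector("list", n)        # reported qualities, file orientation
  alnMask <- vector("list", n)      # aligned file positions
  rpList <- vector("list", n)       # reference position per file position
  errList <- list()
  kindV <- meta$kind; clipV <- meta$clip; strandV <- meta$s
  ctV <- meta$ct; uV <- meta$u; qnV <- meta$qname; mateV <- meta$mate
  for (r in seq_len(n)) {
    q <- .sampleFrom(qualSet, readLen)
    qList[[r]] <- q
    quals[r] <- intToUtf8(q + 33L)
    if (kindV[r] %in% c("unmapped", "unmappedMate")) {
      seqs[r] <- .randSeq(readLen)
      pos[r] <- 0L; cig[r] <- "*"
      alnMask[[r]] <- rep(FALSE, readLen)
      rpList[[r]] <- rep(NA_integer_, readLen)
      next
    }
    c0 <- clipV[r]
    mlen <- readLen - c0
    if (strandV[r] == "F") {
      # raw read spans [u, u+readLen-1]; the first c0 sequenced bases are
      # clipped, so the alignment starts at u + c0
      p <- uV[r] + c0
      cig[r] <- if (c0 > 0L) sprintf("%dS%dM", c0, mlen) else sprintf("%dM", mlen)
      alnFilePos <- (c0 + 1L):readLen
      cycles <- seq_len(readLen)
    } else {
      # raw read spans [u-readLen+1, u] with its 5' end at u; clipping the
      # first c0 sequenced bases trims the high-coordinate end, so the
      # alignment covers [u-readLen+1, u-c0]
      p <- uV[r] - readLen + 1L
      cig[r] <- if (c0 > 0L) sprintf("%dM%dS", mlen, c0) else sprintf("%dM", mlen)
      alnFilePos <- seq_len(mlen)
      cycles <- rev(seq_len(readLen))
    }
    pos[r] <- p
    refpos <- p:(p + mlen - 1L)
    baseV <- strsplit(.randSeq(readLen), "", fixed = TRUE)[[1L]]
    refChars <- strsplit(substr(reference[[ctV[r]]], p, p + mlen - 1L),
                         "", fixed = TRUE)[[1L]]
    baseV[alnFilePos] <- refChars
    # vectorized planting over the aligned bases
    alt <- if (length(altAt)) unname(altAt[paste(ctV[r], refpos)])
           else rep(NA_character_, mlen)
    isAltSite <- !is.na(alt)
    draw <- runif(mlen)
    qa <- q[alnFilePos]; cyc <- cycles[alnFilePos]
    plantAlt <- isAltSite & draw < knownSitesProfile$altFraction
    rate <- 10^(-qa / 10) * ifelse(cyc %in% boostC, boostF, 1)
    plantErr <- !isAltSite & draw < rate
    if (any(plantAlt)) baseV[alnFilePos[plantAlt]] <- alt[plantAlt]
    for (k in which(plantErr))
      baseV[alnFilePos[k]] <- .otherBase(refChars[k])
    hit <- which(plantAlt | plantErr)
    if (length(hit))
      errList[[length(errList) + 1L]] <- list(
        r = r, refpos = refpos[hit], cycle = cyc[hit], q = qa[hit],
        alt = plantAlt[hit])
    seqs[r] <- paste(baseV, collapse = "")
    am <- rep(FALSE, readLen); am[alnFilePos] <- TRUE
    alnMask[[r]] <- am
    rp <- rep(NA_integer_, readLen); rp[alnFilePos] <- refpos
    rpList[[r]] <- rp
  }
  meta$score <- vapply(qList, function(q) sum(q[q >= 15L]), numeric(1))
  errors <- if (length(errList)) {
    lens <- vapply(errList, function(e) length(e$refpos), integer(1))
    rr <- rep(vapply(errList, `[[`, integer(1), "r"), lens)
    data.frame(qname = qnV[rr], mate = mateV[rr], contig = ctV[rr],
               refpos = unlist(lapply(errList, `[[`, "refpos")),
               cycle = unlist(lapply(errList, `[[`, "cycle")),
               q = unlist(lapply(errList, `[[`, "q")),
               kind = ifelse(unlist(lapply(errList, `[[`, "alt")),
                             "alt", "error"),
               stringsAsFactors = FALSE)
  } else
    data.frame(qname = character(0), mate = integer(0), contig = character(0),
               refpos = integer(0), cycle = integer(0), q = integer(0),
               kind = character(0), stringsAsFactors = FALSE)

  # ---- assemble SAM fields (vectorized over records) ----
  lib <- setNames(readGroups$LB, readGroups$ID)
  meta$lib <- unname(lib[meta$rg])
  kind <- meta$kind
  mateRowOf <- match(paste(meta$qname, 3L - meta$mate),
                     paste(meta$qname, meta$mate))
  mr <- mateRowOf
  roleBit <- ifelse(meta$mate == 1L, 0x40L, 0x80L)
  mateRev <- !is.na(mr) & meta$s[mr] %in% "R"
  flag <- integer(n)
  rname <- rep("*", n); rnext <- rep("*", n)
  pnext <- integer(n); tlen <- integer(n)
  isUn <- kind == "unmapped"
  flag[isUn] <- 0x4L
  isUM <- kind == "unmappedMate"
  flag[isUM] <- bitwOr(bitwOr(0x1L, 0x4L), roleBit[isUM]) +
    ifelse(mateRev[isUM], 0x20L, 0L)
  rnext[isUM] <- meta$ct[mr[isUM]]
  pnext[isUM] <- pos[mr[isUM]]
  mapped <- !isUn & !isUM
  rname[mapped] <- meta$ct[mapped]
  flag[mapped] <- ifelse(meta$s[mapped] == "R", 0x10L, 0L)
  isPr <- kind == "pair"
  mrSafe <- ifelse(is.na(mr), 1L, mr)
  sameCt <- isPr & !is.na(mr) & meta$ct == meta$ct[mrSafe]
  sameCt[is.na(sameCt)] <- FALSE
  flag[isPr] <- flag[isPr] + 0x1L + roleBit[isPr] +
    ifelse(mateRev[isPr], 0x20L, 0L) + ifelse(sameCt[isPr], 0x2L, 0L)
  rnext[isPr] <- ifelse(sameCt[isPr], "=", meta$ct[mr[isPr]])
  pnext[isPr] <- pos[mr[isPr]]
  same <- which(sameCt)
  if (length(same)) {
    lo <- pmin(pos[same], pos[mr[same]])
    hi <- pmax(pos[same] + readLen - meta$clip[same],
               pos[mr[same]] + readLen - meta$clip[mr[same]]) - 1L
    tlen[same] <- ifelse(pos[same] <= pos[mr[same]], hi - lo + 1L,
                         -(hi - lo + 1L))
  }
  isPF <- kind == "pairFrag"
  flag[isPF] <- flag[isPF] + 0x1L + 0x8L + roleBit[isPF]
  rnext[isPF] <- "="
  pnext[isPF] <- pos[isPF]
  aln0 <- data.frame(
    qname = meta$qname, flag = flag, rname = rname, pos = pos,
    mapq = meta$mapq, cigar = cig, rnext = rnext, pnext = pnext,
    tlen = tlen, seq = seqs, qual = quals,
    tags = paste0("RG:Z:", meta$rg), stringsAsFactors = FALSE)

  # secondary copies of random mapped reads
  nSec <- round(fracSecondary * nPairs)
  secFrom <- if (nSec > 0L)
    .sampleFrom(which(!meta$kind %in% c("unmapped", "unmappedMate")), nSec,
                replace = FALSE)
  else integer(0)
  alnFull <- aln0
  if (length(secFrom)) {
    secondary <- aln0[secFrom, , drop = FALSE]
    secondary$flag <- bitwOr(secondary$flag, 0x100L)
    secondary$mapq <- 0L
    alnFull <- rbind(aln0, secondary)
  }
  src <- c(seq_len(n), secFrom)
  isSec <- c(rep(FALSE, n), rep(TRUE, length(secFrom)))

  # shuffle into final file order
  ord <- sample.int(nrow(alnFull))
  alnFull <- alnFull[ord, , drop = FALSE]
  src <- src[ord]; isSec <- isSec[ord]
  alnFull$fileIndex <- seq_len(nrow(alnFull)) - 1L
  rownames(alnFull) <- NULL
  meta$fileIndex <- NA_integer_
  meta$fileIndex[src[!isSec]] <- alnFull$fileIndex[!isSec]

  header <- new("SamHeader", lines = c(
    "@HD\tVN:1.6",
    paste0("@SQ\tSN:", contigs, "\tLN:", unname(clen)),
    paste0("@RG\tID:", readGroups$ID, "\tLB:", readGroups$LB,
           "\tPU:", readGroups$PU)))
  sam <- new("SamFile", header = header, alignments = alnFull)

  # ---- duplicate truth (generator space, file-order tie-break) ----
  meta$truthDup <- FALSE
  isPairRead <- meta$kind == "pair"
  mates1 <- which(isPairRead & meta$mate == 1L)
  pairTbl <- if (length(mates1)) {
    r1 <- mates1; r2 <- mateRowOf[mates1]
    c1 <- match(meta$ct[r1], contigs); c2 <- match(meta$ct[r2], contigs)
    firstLE <- (c1 < c2) | (c1 == c2 & (meta$u[r1] < meta$u[r2] |
                 (meta$u[r1] == meta$u[r2] & meta$s[r1] <= meta$s[r2])))
    ea <- ifelse(firstLE, r1, r2); eb <- ifelse(firstLE, r2, r1)
    data.frame(
      qname = meta$qname[r1], lib = meta$lib[r1], rg = meta$rg[r1],
      key = paste(meta$lib[r1],
                  paste(meta$ct[ea], meta$u[ea], meta$s[ea], sep = ":"),
                  paste(meta$ct[eb], meta$u[eb], meta$s[eb], sep = ":"),
                  sep = "|"),
      score = meta$score[r1] + meta$score[r2],
      pairIndex = pmin(meta$fileIndex[r1], meta$fileIndex[r2]),
      r1 = r1, r2 = r2, stringsAsFactors = FALSE)
  } else data.frame(qname = character(0), lib = character(0),
                    rg = character(0), key = character(0),
                    score = numeric(0), pairIndex = integer(0),
                    r1 = integer(0), r2 = integer(0))
  if (nrow(pairTbl)) {
    po <- order(pairTbl$key, -pairTbl$score, pairTbl$pairIndex,
                method = "radix")
    isDup <- logical(nrow(pairTbl)); isDup[po] <- duplicated(pairTbl$key[po])
    pairTbl$isDup <- isDup
    meta$truthDup[pairTbl$r1] <- isDup
    meta$truthDup[pairTbl$r2] <- isDup
  } else pairTbl$isDup <- logical(0)
  pairEndKeysTruth <- unique(c(
    paste(meta$lib[isPairRead], meta$ct[isPairRead], meta$u[isPairRead],
          meta$s[isPairRead], sep = "|")))
  fragRows <- which(meta$kind %in% c("frag", "pairFrag"))
  if (length(fragRows)) {
    fkey <- paste(meta$lib[fragRows], meta$ct[fragRows], meta$u[fragRows],
                  meta$s[fragRows], sep = "|")
    beaten <- fkey %in% pairEndKeysTruth
    meta$truthDup[fragRows[beaten]] <- TRUE
    free <- which(!beaten)
    if (length(free)) {
      fo <- free[order(fkey[free], -meta$score[fragRows][free],
                       meta$fileIndex[fragRows][free], method = "radix")]
      meta$truthDup[fragRows[fo]] <- meta$truthDup[fragRows[fo]] |
        duplicated(fkey[fo])
    }
  }

  # ---- optical truth ----
  optTruth <- numeric(0)
  md <- op$maxDistance
  for (k in unique(pairTbl$key[duplicated(pairTbl$key)])) {
    ix <- which(pairTbl$key == k)
    mm <- length(ix)
    t1 <- meta$tile[pairTbl$r1[ix]]; x1 <- meta$x[pairTbl$r1[ix]]
    y1 <- meta$y[pairTbl$r1[ix]]; rg1 <- pairTbl$rg[ix]
    parent <- seq_len(mm)
    root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_len(mm - 1L)) for (b in (a + 1L):mm) {
      if (is.na(t1[a]) || is.na(t1[b])) next
      if (t1[a] == t1[b] && rg1[a] == rg1[b] &&
          abs(x1[a] - x1[b]) <= md && abs(y1[a] - y1[b]) <= md) {
        ra <- root(a); rb <- root(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_len(mm), root, integer(1))
    l <- pairTbl$lib[ix[1L]]
    optTruth[l] <- sum(optTruth[l], na.rm = TRUE) + sum(table(roots) - 1L)
  }

  # ---- per-bin aligned-base tallies over tabulation-eligible reads ----
  eligible <- which(meta$kind %in% c("pair", "pairFrag", "frag") &
                    meta$mapq > 0L & !meta$truthDup)
  errorKeys <- paste(errors$qname, errors$mate, errors$refpos)[
    errors$kind == "error"]
  bc <- vector("list", length(eligible)); maskedObs <- 0L
  metaCt <- meta$ct; metaS <- meta$s; metaMate <- meta$mate
  metaRg <- meta$rg; metaQn <- meta$qname
  for (i in seq_along(eligible)) {
    r <- eligible[i]
    j <- which(alnMask[[r]])
    rp <- rpList[[r]][j]
    mk <- maskFull[[metaCt[r]]]
    masked <- if (!is.null(mk)) rp %in% mk else rep(FALSE, length(rp))
    maskedObs <- maskedObs + sum(masked)
    j <- j[!masked]; rp <- rp[!masked]
    if (!length(j)) next
    cyc <- if (metaS[r] == "F") j else readLen - j + 1L
    if (metaMate[r] == 2L) cyc <- -cyc
    bc[[i]] <- list(r = r, q = qList[[r]][j], cycle = cyc, rp = rp)
  }
  bc <- bc[!vapply(bc, is.null, logical(1))]
  baseCounts <- if (length(bc)) {
    lens <- vapply(bc, function(e) length(e$q), integer(1))
    rr <- rep(vapply(bc, `[[`, integer(1), "r"), lens)
    dtt <- data.table::data.table(
      rg = metaRg[rr],
      q = unlist(lapply(bc, `[[`, "q")),
      cycle = unlist(lapply(bc, `[[`, "cycle")),
      err = paste(metaQn[rr], metaMate[rr],
                  unlist(lapply(bc, `[[`, "rp"))) %in% errorKeys)
    out <- dtt[, list(obs = as.numeric(.N), err = as.numeric(sum(err))),
               by = c("rg", "q", "cycle")]
    data.table::setorderv(out, c("rg", "q", "cycle"))
    as.data.frame(out)
  } else data.frame(rg = character(0), q = integer(0), cycle = integer(0),
                    obs = numeric(0), err = numeric(0))

  # ---- VCF of the planted sites ----
  vcf <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", contigs, ",length=", unname(clen), ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(sites)) {
    refAllele <- vapply(seq_len(nrow(sites)), function(i)
      substr(reference[[sites$contig[i]]], sites$pos[i],
             sites$pos[i] + sites$span[i] - 1L), character(1))
    altAllele <- ifelse(sites$span == 1L, sites$altBase,
                        substr(refAllele, 1L, 1L))
    vcf <- c(vcf, paste(sites$contig, sites$pos, ".", refAllele, altAllele,
                        "100", "PASS", ".", sep = "\t"))
  }

  list(sam = sam, reads = meta, opticalTruth = optTruth,
       baseCounts = baseCounts, maskedObs = maskedObs, errors = errors,
       sites = sites[c("contig", "pos", "span")], vcf = vcf)
}
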