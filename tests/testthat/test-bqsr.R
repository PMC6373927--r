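# Base quality score recalibration: tabulation, empirical quality,
# hierarchical deltas, application, and the .recal report dialect.

test_that("tabulation counts aligned matching/mismatching bases", {
  ref <- c(chr1 = strrep("A", 200))
  q30 <- phredStr(rep(30L, 4L))
  sam <- mkSam(list(mkRecord(qname = "r", pos = 100L, cigar = "4M",
                             seq = "AAAA", qual = q30, tags = "RG:Z:rg1")))
  tab <- bqsrTabulate(sam, ref, NULL)
  expect_equal(tab@global$obs, 4)
  expect_equal(tab@global$err, 0)
  expect_equal(tab@byQ$obs, 4)
  expect_equal(tab@byQ$q, 30L)
  # one mismatch at a known-site position: base masked entirely
  sam2 <- mkSam(list(mkRecord(qname = "r", pos = 100L, cigar = "4M",
                              seq = "AGAA", qual = q30, tags = "RG:Z:rg1")))
  ks <- new("KnownSites", sites = data.frame(contig = "chr1", pos = 101L,
                                             span = 1L))
  tab2 <- bqsrTabulate(sam2, ref, ks)
  expect_equal(tab2@global$obs, 3)
  expect_equal(tab2@global$err, 0)
  # without masking the mismatch is an error
  tab3 <- bqsrTabulate(sam2, ref, NULL)
  expect_equal(tab3@global$err, 1)
  # a deletion-allele span masks every covered base
  ks2 <- new("KnownSites", sites = data.frame(contig = "chr1", pos = 100L,
                                              span = 2L))
  expect_equal(bqsrTabulate(sam2, ref, ks2)@global$obs, 2)
})

test_that("tabulation skips duplicates, secondary, mapq0 and clipped bases", {
  ref <- c(chr1 = strrep("A", 200))
  q <- phredStr(rep(30L, 6L))
  recs <- list(
    mkRecord(qname = "ok", pos = 100L, cigar = "2S4M", seq = "TTAAAA",
             qual = phredStr(rep(30L, 6L)), tags = "RG:Z:rg1"),
    mkRecord(qname = "dup", flag = 0x400L, pos = 100L, cigar = "6M",
             seq = "AAAAAA", qual = q, tags = "RG:Z:rg1"),
    mkRecord(qname = "sec", flag = 0x100L, pos = 100L, cigar = "6M",
             seq = "AAAAAA", qual = q, tags = "RG:Z:rg1"),
    mkRecord(qname = "m0", pos = 100L, mapq = 0L, cigar = "6M",
             seq = "AAAAAA", qual = q, tags = "RG:Z:rg1"))
  tab <- bqsrTabulate(mkSam(recs), ref, NULL)
  expect_equal(tab@global$obs, 4)       # only the 4 aligned bases of "ok"
  # insertions contribute nothing; deletions advance the reference
  sam2 <- mkSam(list(mkRecord(qname = "id", pos = 100L, cigar = "2M2I2M2D2M",
                              seq = "AATTAAAA", qual = phredStr(rep(30L, 8L)),
                              tags = "RG:Z:rg1")))
  expect_equal(bqsrTabulate(sam2, ref, NULL)@global$obs, 6)
  # missing contig is an error
  expect_error(bqsrTabulate(mkSam(list(mkRecord(rname = "chr2"))),
                            ref, NULL), "missing from reference")
})

test_that("reverse-strand cycles count from the sequencing start", {
  ref <- c(chr1 = strrep("A", 200))
  # reverse read: file position j has cycle L - j + 1
  sam <- mkSam(list(mkRecord(qname = "r", flag = 0x10L, pos = 100L,
                             cigar = "4M", seq = "GAAA",
                             qual = phredStr(c(10L, 20L, 30L, 40L)),
                             tags = "RG:Z:rg1")))
  tab <- bqsrTabulate(sam, ref, NULL)
  # the mismatching G sits at file pos 1 = cycle 4, reported quality 10
  erow <- tab@byCycle[tab@byCycle$err == 1, ]
  expect_equal(erow$cycle, 4L)
  expect_equal(erow$q, 10L)
  # second-of-pair cycles are negated
  sam2 <- mkSam(list(mkRecord(qname = "r", flag = bitwOr(0x1L, 0x80L),
                              pos = 100L, cigar = "4M", seq = "AAAA",
                              qual = phredStr(rep(30L, 4L)), tags = "RG:Z:rg1")))
  expect_true(all(bqsrTabulate(sam2, ref, NULL)@byCycle$cycle < 0))
})

test_that("table counts are conserved across covariate levels", {
  sim <- simReads(simReference(seed = 17), nPairs = 60L, seed = 17)
  ref <- simReference(seed = 17)
  marked <- markDuplicates(sim$sam)$sam
  tab <- bqsrTabulate(marked, ref, readVcfSites(sim$vcf))
  sumBy <- function(df) sum(df$obs)
  expect_equal(sum(tab@byQ$obs), sum(tab@global$obs))
  expect_equal(sum(tab@byCycle$obs), sum(tab@global$obs))
  expect_equal(sum(tab@byContext$obs), sum(tab@global$obs))
  expect_equal(sum(tab@byQ$err), sum(tab@global$err))
  expect_equal(sum(tab@byCycle$err), sum(tab@global$err))
  expect_equal(sum(tab@byContext$err), sum(tab@global$err))
  # per-parent conservation, not just grand totals
  dtQ <- aggregate(cbind(obs, err) ~ rg, tab@byQ, sum)
  m <- match(dtQ$rg, tab@global$rg)
  expect_equal(dtQ$obs, tab@global$obs[m])
  dtC <- aggregate(cbind(obs, err) ~ rg + q, tab@byCycle, sum)
  key <- paste(tab@byQ$rg, tab@byQ$q)
  m2 <- match(paste(dtC$rg, dtC$q), key)
  expect_equal(dtC$obs, tab@byQ$obs[m2])
  expect_equal(dtC$err, tab@byQ$err[m2])
})

test_that("tabulation is invariant under record shuffling", {
  sim <- simReads(simReference(seed = 18), nPairs = 50L, seed = 18)
  ref <- simReference(seed = 18)
  tab1 <- bqsrTabulate(sim$sam, ref, NULL)
  sh <- sim$sam
  set.seed(5)
  alignments(sh) <- alignments(sim$sam)[sample.int(nrow(alignments(sim$sam))), ]
  tab2 <- bqsrTabulate(sh, ref, NULL)
  for (s in c("global", "byQ", "byCycle", "byContext"))
    expect_equal(slot(tab2, s), slot(tab1, s))
})

test_that("tabulation agrees with the generator's per-base tally", {
  ref <- simReference(seed = 19)
  sim <- simReads(ref, nPairs = 120L, seed = 19)
  marked <- markDuplicates(sim$sam)$sam
  # generator truth excludes its known duplicates; verify flags match first
  tab <- bqsrTabulate(marked, ref, readVcfSites(sim$vcf))
  truth <- sim$baseCounts
  got <- tab@byCycle
  gk <- paste(got$rg, got$q, got$cycle)
  tk <- paste(truth$rg, truth$q, truth$cycle)
  expect_setequal(gk, tk)
  m <- match(gk, tk)
  expect_equal(got$obs, truth$obs[m])
  expect_equal(got$err, truth$err[m])
  # masking removed exactly the planted-site observations
  tabNoMask <- bqsrTabulate(marked, ref, NULL)
  expect_equal(sum(tabNoMask@global$obs) - sum(tab@global$obs),
               sim$maskedObs)
})

test_that("empirical quality maximizes the stated posterior", {
  # zero observations: prior centre passes through
  expect_equal(empiricalQuality(0, 0, 30), 30)
  expect_equal(empiricalQuality(0, 0, 27.35), 27.35)
  # independent exhaustive scan of the objective
  scan <- function(obs, err, prior, sigma = 0.5) {
    best <- -Inf; bestQ <- NA
    for (Q in 0:93) {
      v <- dnorm(Q, prior, sigma, log = TRUE) +
        dbinom(err, obs, 10^(-Q / 10), log = TRUE)
      if (v > best) { best <- v; bestQ <- Q }
    }
    bestQ
  }
  cases <- list(c(1000, 1, 30), c(1000, 100, 30), c(50, 0, 25),
                c(10000, 10, 30), c(100, 99, 20))
  for (cs in cases)
    expect_equal(empiricalQuality(cs[1], cs[2], cs[3]),
                 scan(cs[1], cs[2], cs[3]), info = paste(cs, collapse = "/"))
  # likelihood peak at the prior centre stays put
  expect_equal(empiricalQuality(1e6, 1e6 * 10^(-3), 30), 30)
})

test_that("deltas vanish on calibrated data", {
  ref <- simReference(c(chrA = 30000L), seed = 20)
  # clean, calibrated data: one reported quality whose planted error rate
  # is exactly 10^(-q/10), no duplicates. (With a mixture of reported
  # qualities the global bin legitimately drifts: the empirical quality of
  # a rate mixture is below the mean reported quality; the vanishing-delta
  # property is a per-bin statement.)
  sim <- simReads(ref, nPairs = 700L, readLen = 80L,
                  dupProfile = list(nGroups = 0L, sizeRange = c(2L, 2L),
                                    clipMax = 2L),
                  fracCrossContig = 0, fracMateUnmapped = 0,
                  fracUnmappedSingles = 0, fracSecondary = 0, fracMapq0 = 0,
                  knownSitesProfile = list(n = 0L, altFraction = 0,
                                           fracSpan2 = 0),
                  errorProfile = list(qualities = 25L,
                                      boostCycles = integer(0),
                                      boostFactor = 1),
                  seed = 20)
  tab <- bqsrTabulate(sim$sam, ref, NULL)
  expect_gt(sum(tab@global$obs), 1e5)
  rec <- computeDeltas(tab)
  expect_true(all(abs(rec@global$delta) <= 1))
  expect_true(all(abs(rec@byQ$delta) <= 1))
  expect_true(all(abs(rec@byCycle$delta) <= 1))
  expect_true(all(abs(rec@byContext$delta) <= 1))
})

test_that("an injected per-cycle error boost is recovered within one Phred", {
  # one read group, one reported quality, short reads: concentrates the
  # observations so the per-cycle empirical quality is evidence-dominated
  ref <- simReference(c(chrA = 60000L), seed = 24)
  sim <- simReads(ref, nPairs = 8000L, readLen = 30L,
                  fragmentRange = c(70L, 110L),
                  readGroups = data.frame(ID = "rg1", LB = "libA", PU = "u1"),
                  dupProfile = list(nGroups = 0L, sizeRange = c(2L, 2L),
                                    clipMax = 0L),
                  fracUnpaired = 0, fracCrossContig = 0,
                  fracMateUnmapped = 0, fracUnmappedSingles = 0,
                  fracSecondary = 0, fracMapq0 = 0,
                  knownSitesProfile = list(n = 0L, altFraction = 0,
                                           fracSpan2 = 0),
                  errorProfile = list(qualities = 20L, boostCycles = 15L,
                                      boostFactor = 10),
                  seed = 24)
  rec <- computeDeltas(bqsrTabulate(sim$sam, ref, NULL))
  bc <- rec@byCycle
  pred <- 20 + rec@global$delta + rec@byQ$delta[match(bc$q, rec@byQ$q)] +
    bc$delta
  # boosted cycle: 10x the q20 error rate is a true quality of 10
  expect_true(all(abs(pred[abs(bc$cycle) == 15L] - 10) <= 1))
  # every other cycle stays calibrated at 20
  expect_true(all(abs(pred[abs(bc$cycle) != 15L] - 20) <= 1))
})

test_that("application rewrites only QUAL, honors preservation and clamping", {
  # hand-built table: rg1, q30 -> deltas summing to -2
  tbl <- new("RecalTable",
             global = data.frame(rg = "rg1", obs = 100, err = 1, sumQ = 3000,
                                 empQ = 28, delta = -2, estQ = 30),
             byQ = data.frame(rg = "rg1", q = 30L, obs = 100, err = 1,
                              empQ = 28, delta = 0),
             byCycle = data.frame(rg = character(0), q = integer(0),
                                  cycle = integer(0), obs = numeric(0),
                                  err = numeric(0), empQ = numeric(0),
                                  delta = numeric(0)),
             byContext = data.frame(rg = character(0), q = integer(0),
                                    context = character(0), obs = numeric(0),
                                    err = numeric(0), empQ = numeric(0),
                                    delta = numeric(0)),
             params = list(context = 2L, hasDeltas = TRUE, sigma = 0.5))
  sam <- mkSam(list(
    mkRecord(qname = "a", pos = 10L, cigar = "4M", seq = "ACGT",
             qual = phredStr(c(30L, 30L, 2L, 30L)), tags = "RG:Z:rg1"),
    mkRecord(qname = "dup", flag = 0x400L, pos = 10L, cigar = "4M",
             seq = "ACGT", qual = phredStr(rep(30L, 4L)), tags = "RG:Z:rg1"),
    mkRecord(qname = "un", flag = 0x4L, rname = "*", pos = 0L, cigar = "*",
             seq = "ACGT", qual = phredStr(rep(30L, 4L)), tags = "RG:Z:rg1"),
    mkRecord(qname = "norg", pos = 10L, cigar = "4M", seq = "ACGT",
             qual = phredStr(rep(30L, 4L)))))
  out <- applyBqsr(sam, tbl, preserveBelow = 6L)
  a0 <- alignments(sam); a1 <- alignments(out)
  expect_identical(a1[setdiff(names(a1), "qual")],
                   a0[setdiff(names(a0), "qual")])
  # q30 -> 28; q2 preserved; duplicates and unmapped recalibrated too;
  # unknown read group left alone
  expect_equal(a1$qual[1L], phredStr(c(28L, 28L, 2L, 28L)))
  expect_equal(a1$qual[2L], phredStr(rep(28L, 4L)))
  expect_equal(a1$qual[3L], phredStr(rep(28L, 4L)))
  expect_equal(a1$qual[4L], a0$qual[4L])
  # all-zero deltas are the identity
  tbl0 <- tbl
  tbl0@global$delta <- 0
  expect_identical(alignments(applyBqsr(sam, tbl0))$qual, a0$qual)
  # clamping: big negative delta floors at 1
  tblNeg <- tbl
  tblNeg@global$delta <- -50
  expect_equal(alignments(applyBqsr(sam, tblNeg))$qual[2L],
               phredStr(rep(1L, 4L)))
})

test_that("missing sub-bins fall back to the deepest available ancestor", {
  ref <- simReference(seed = 21)
  sim <- simReads(ref, nPairs = 40L, seed = 21)
  tab <- computeDeltas(bqsrTabulate(sim$sam, ref, NULL))
  # a read whose cycle/context bins cannot exist (fresh synthetic read)
  sam <- mkSam(list(mkRecord(qname = "x", pos = 50L, cigar = "4M",
                             seq = "ACGT", qual = phredStr(rep(99L %% 60L, 4L)),
                             tags = "RG:Z:rg1")))
  out <- applyBqsr(sam, tab)
  # q=39 has no bin anywhere in the sim tables -> only the global delta applies
  dG <- tab@global$delta[tab@global$rg == "rg1"]
  want <- pmin(pmax(floor(39 + dG + 0.5), 1L), 93L)
  expect_equal(utf8ToInt(alignments(out)$qual) - 33L, rep(want, 4L))
})

test_that("recal reports round trip and are byte-stable across runs", {
  ref <- simReference(seed = 22)
  sim <- simReads(ref, nPairs = 50L, seed = 22)
  tab <- computeDeltas(bqsrTabulate(markDuplicates(sim$sam)$sam, ref,
                                    readVcfSites(sim$vcf)))
  p1 <- withr::local_tempfile(fileext = ".recal")
  p2 <- withr::local_tempfile(fileext = ".recal")
  writeRecalTable(tab, p1)
  back <- readRecalTable(p1)
  for (s in c("global", "byQ", "byCycle", "byContext"))
    expect_equal(slot(back, s), slot(tab, s))
  expect_equal(back@params$context, tab@params$context)
  writeRecalTable(back, p2)
  expect_identical(readLines(p2), readLines(p1))
  # counts-only tables round trip too
  raw <- bqsrTabulate(sim$sam, ref, NULL)
  writeRecalTable(raw, p1)
  back2 <- readRecalTable(p1)
  expect_equal(back2@global, raw@global)
  expect_equal(back2@byContext, raw@byContext)
  # empty table -> header-only report, still parseable
  emptyTab <- bqsrTabulate(mkSam(list()), c(chr1 = "AAAA"), NULL)
  writeRecalTable(emptyTab, p1)
  expect_equal(nrow(readRecalTable(p1)@global), 0L)
  # malformed section header is a parse error
  writeLines(c("#:samforge.recal:v1", "#:context:2", "#:deltas:no",
               "## ReadGroupTable"), p1)
  expect_error(readRecalTable(p1), "parse error")
})

test_that("quantization snaps recalibrated qualities to learned levels", {
  lv <- learnQuantizationLevels(c(rep(20L, 50), rep(30L, 50), rep(40L, 5)), 2L)
  expect_length(lv, 2L)
  expect_true(all(lv >= 20 & lv <= 40))
  expect_equal(learnQuantizationLevels(c(10L, 20L), 5L), c(10L, 20L))
})
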