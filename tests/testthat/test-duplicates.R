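# Duplicate marking, optical clustering, library-size estimation.

test_that("unclipped position undoes 5' clipping on both strands", {
  fwd <- mkSam(list(mkRecord(pos = 100L, cigar = "10M"),
                    mkRecord(pos = 100L, cigar = "3S7M"),
                    mkRecord(pos = 100L, cigar = "2H3S5M",
                             seq = strrep("A", 8), qual = strrep("I", 8))))
  expect_equal(unclippedPosition(fwd), c(100L, 97L, 95L))
  rev <- mkSam(list(mkRecord(flag = 0x10L, pos = 100L, cigar = "5M2S",
                             seq = strrep("A", 7), qual = strrep("I", 7)),
                    mkRecord(flag = 0x10L, pos = 100L, cigar = "5M"),
                    mkRecord(flag = 0x10L, pos = 100L, cigar = "3M2D2M1S",
                             seq = strrep("A", 6), qual = strrep("I", 6))))
  # reverse: pos + refLen - 1 + trailing clips; D consumes reference
  expect_equal(unclippedPosition(rev), c(106L, 104L, 107L))
  un <- mkSam(list(mkRecord(flag = 0x4L, rname = "*", pos = 0L, cigar = "*",
                            seq = "AAAA", qual = "IIII")))
  expect_error(unclippedPosition(un), "unmapped")
})

test_that("record score sums qualities at or above 15", {
  expect_equal(recordScore(phredStr(c(20L, 20L, 10L))), 40)
  expect_equal(recordScore(phredStr(rep(14L, 10L))), 0)
  expect_equal(recordScore("*"), 0)
  expect_equal(recordScore(phredStr(c(15L, 15L))), 30)
  # pair additivity is by construction score(m1)+score(m2)
  expect_equal(recordScore(phredStr(40)) + recordScore(phredStr(30)), 70)
})

test_that("duplicate marking picks the best-scoring survivor", {
  sam <- mkSam(list(
    mkRecord(qname = "hi", pos = 100L, cigar = "4M", qual = phredStr(rep(20L, 4))),
    mkRecord(qname = "lo", pos = 100L, cigar = "4M", qual = phredStr(rep(16L, 4)))))
  res <- markDuplicates(sam)
  expect_equal(isDuplicate(alignments(res$sam)$flag), c(FALSE, TRUE))
  # survivors get the flag cleared if it was set
  pre <- sam
  a <- alignments(pre); a$flag[1L] <- bitwOr(a$flag[1L], 0x400L)
  alignments(pre) <- a
  res2 <- markDuplicates(pre)
  expect_equal(isDuplicate(alignments(res2$sam)$flag), c(FALSE, TRUE))
})

test_that("a fragment on a pair-end key is marked even when it scores higher", {
  q30 <- phredStr(rep(30L, 10L))
  q40 <- phredStr(rep(40L, 10L))
  sam <- mkSam(list(
    mkRecord(qname = "p", flag = bitwOr(0x1L, 0x20L), pos = 100L,
             cigar = "10M", rnext = "=", pnext = 160L, qual = q30),
    mkRecord(qname = "p", flag = bitwOr(0x1L, bitwOr(0x10L, 0x80L)),
             pos = 160L, cigar = "10M", rnext = "=", pnext = 100L, qual = q30),
    mkRecord(qname = "f", flag = 0L, pos = 102L, cigar = "2S8M", qual = q40)))
  res <- markDuplicates(sam)
  expect_equal(isDuplicate(alignments(res$sam)$flag), c(FALSE, FALSE, TRUE))
  expect_true(res$fragments$isDup)
})

test_that("score ties break deterministically by file order and repeat identically", {
  q <- phredStr(rep(25L, 10L))
  mk <- function() mkSam(list(
    mkRecord(qname = "a1", flag = bitwOr(0x1L, 0x20L), pos = 100L,
             cigar = "10M", rnext = "=", pnext = 150L, qual = q),
    mkRecord(qname = "b1", flag = bitwOr(0x1L, 0x20L), pos = 100L,
             cigar = "10M", rnext = "=", pnext = 150L, qual = q),
    mkRecord(qname = "a1", flag = bitwOr(0x1L, bitwOr(0x10L, 0x80L)),
             pos = 150L, cigar = "10M", rnext = "=", pnext = 100L, qual = q),
    mkRecord(qname = "b1", flag = bitwOr(0x1L, bitwOr(0x10L, 0x80L)),
             pos = 150L, cigar = "10M", rnext = "=", pnext = 100L, qual = q)))
  r1 <- markDuplicates(mk(), deterministic = TRUE)
  r2 <- markDuplicates(mk(), deterministic = TRUE)
  expect_identical(samLines(r1$sam), samLines(r2$sam))
  flags <- isDuplicate(alignments(r1$sam)$flag)
  expect_equal(flags, c(FALSE, TRUE, FALSE, TRUE))   # lower ordinal survives
})

test_that("mate-absent paired records are treated as fragments with a warning", {
  q <- phredStr(rep(30L, 10L))
  sam <- mkSam(list(
    mkRecord(qname = "widow", flag = 0x1L, pos = 100L, cigar = "10M", qual = q),
    mkRecord(qname = "solo", flag = 0L, pos = 100L, cigar = "10M",
             qual = phredStr(rep(20L, 10L)))))
  res <- markDuplicates(sam)
  expect_match(res$warnings, "without a usable mate")
  # both compete as fragments on the same key
  expect_equal(isDuplicate(alignments(res$sam)$flag), c(FALSE, TRUE))
})

test_that("marking changes only the duplicate bit and never record count", {
  sim <- simReads(simReference(seed = 12), nPairs = 60L, seed = 12)
  res <- markDuplicates(sim$sam)
  a0 <- alignments(sim$sam); a1 <- alignments(res$sam)
  expect_equal(nrow(a1), nrow(a0))
  expect_equal(bitwAnd(a1$flag, bitwNot(0x400L)),
               bitwAnd(a0$flag, bitwNot(0x400L)))
  cols <- setdiff(names(a0), "flag")
  expect_identical(a1[cols], a0[cols])
  # secondary/supplementary/unmapped flags untouched
  skip <- isSecondary(a0$flag) | isSupplementary(a0$flag) | isUnmapped(a0$flag)
  expect_equal(a1$flag[skip], a0$flag[skip])
})

test_that("marking agrees with the exhaustive pairwise oracle on random files", {
  for (seed in 1:12) {
    sam <- randomSamFile(seed, nRecords = 70L)
    res <- markDuplicates(sam, deterministic = TRUE)
    got <- isDuplicate(alignments(res$sam)$flag)
    want <- oracleMarkDuplicates(sam)
    touched <- !is.na(want)
    expect_equal(got[touched], want[touched], info = paste("seed", seed))
  }
})

test_that("classification is invariant under input shuffling", {
  sim <- simReads(simReference(seed = 13), nPairs = 80L, seed = 13)
  res <- markDuplicates(sim$sam, deterministic = TRUE)
  key0 <- alignments(res$sam)
  key0 <- paste(key0$qname, bitwAnd(key0$flag, 0xC0L))[isDuplicate(key0$flag)]
  set.seed(1)
  sh <- sim$sam
  alignments(sh) <- alignments(sim$sam)[sample.int(nrow(alignments(sim$sam))), ]
  res2 <- markDuplicates(sh, deterministic = TRUE)
  key1 <- alignments(res2$sam)
  key1 <- paste(key1$qname, bitwAnd(key1$flag, 0xC0L))[isDuplicate(key1$flag)]
  expect_setequal(key1, key0)
})

test_that("physical locations parse by the last-three-integer rule", {
  loc <- parsePhysicalLocation(c("M:1:FC:1:2101:1000:2000", "read1",
                                 "a:b:c:d:1:2:3", "a:b:c:d:x:2:3"))
  expect_equal(loc$tile, c(2101L, NA, 1L, NA))
  expect_equal(loc$x, c(1000L, NA, 2L, NA))
  expect_equal(loc$y, c(2000L, NA, 3L, NA))
})

test_that("optical linking needs same tile and per-axis distance", {
  sam <- mkSam(mkPairRecs(c("m:1:f:1:1:10:10", "m:2:f:1:1:60:50")))
  dup <- markDuplicates(sam)
  expect_equal(unname(markOpticalDuplicates(dup, 100L)["lib1"]), 1)
  # same coordinates but different tiles never link
  sam2 <- mkSam(mkPairRecs(c("m:1:f:1:1:10:10", "m:2:f:1:2:10:10")))
  expect_equal(unname(markOpticalDuplicates(markDuplicates(sam2), 100L)["lib1"]), 0)
  # rectangle semantics: dx=100, dy=100 links; dx=101 does not
  sam3 <- mkSam(mkPairRecs(c("m:1:f:1:1:0:0", "m:2:f:1:1:100:100",
                             "m:3:f:1:1:301:0")))
  expect_equal(unname(markOpticalDuplicates(markDuplicates(sam3), 100L)["lib1"]), 1)
})

test_that("optical clusters are transitive closures, counted minus one", {
  # chain a-b linked, b-c linked, a-c distant -> one cluster of 3, 2 optical
  sam <- mkSam(mkPairRecs(c("m:1:f:1:1:0:0", "m:2:f:1:1:90:0",
                            "m:3:f:1:1:180:0")))
  dup <- markDuplicates(sam)
  expect_equal(unname(markOpticalDuplicates(dup, 100L)["lib1"]), 2)
  # members without locations are never linked
  sam2 <- mkSam(mkPairRecs(c("noloc1", "noloc2")))
  expect_equal(unname(markOpticalDuplicates(markDuplicates(sam2), 100L)["lib1"]), 0)
})

test_that("optical counts agree with the all-pairs closure oracle on random layouts", {
  set.seed(31)
  for (rep in 1:20) {
    m <- sample(2:7, 1L)
    tiles <- sample(1:2, m, replace = TRUE)
    xs <- sample(0:400, m, replace = TRUE)
    ys <- sample(0:400, m, replace = TRUE)
    qn <- sprintf("m:%d:f:1:%d:%d:%d", seq_len(m), tiles, xs, ys)
    quals <- lapply(seq_len(m), function(i)
      phredStr(rep(sample(20:35, 1L), 10L)))
    sam <- mkSam(mkPairRecs(qn, quals = quals))
    dup <- markDuplicates(sam)
    got <- unname(markOpticalDuplicates(dup, 100L)["lib1"])
    locs <- data.frame(tile = tiles, x = xs, y = ys, rg = "rg1")
    expect_equal(got, oracleOpticalCount(locs, 100L),
                 info = paste("rep", rep))
    # never more optical than pair duplicates
    expect_lte(got, sum(dup$pairs$isDup))
  }
})

test_that("library size solves the saturation equation to tolerance", {
  for (N in c(100, 1e4, 1e6)) for (frac in c(0.2, 0.5, 0.9, 0.99)) {
    U <- round(N * frac)
    X <- estimateLibrarySize(N, U)
    expect_lt(abs(X * (1 - exp(-N / X)) - U), 1e-6 * X)
  }
  expect_true(is.na(estimateLibrarySize(100, 100)))
  expect_true(is.na(estimateLibrarySize(100, 0)))
  expect_error(estimateLibrarySize(100, 101), "exceed")
  # monotone in U at fixed N
  xs <- vapply(c(30, 50, 60, 90), function(u)
    estimateLibrarySize(100, u), numeric(1))
  expect_true(all(diff(xs) > 0))
  expect_gt(estimateLibrarySize(100, 60), estimateLibrarySize(100, 30) )
})
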