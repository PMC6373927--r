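# Plan construction and the single-pass execution core.

test_that("plans canonicalize: option order is irrelevant", {
  o1 <- list(markDuplicates = TRUE, sortingOrder = "coordinate",
             markOpticalDuplicates = TRUE, metricsFile = "m.metrics",
             bqsr = "out.recal", knownSites = "s.vcf",
             bqsrReference = "r.fa", deterministic = TRUE)
  o2 <- rev(o1)
  p1 <- buildPlan(o1); p2 <- buildPlan(o2)
  expect_identical(p1, p2)
  # canonical stage order: sort before duplicate marking before tabulation
  expect_equal(p1@phase2, c("sort", "markDuplicates", "bqsrTabulate"))
  expect_equal(p1@phase3, c("bqsrApply", "metrics"))
})

test_that("invalid option combinations are configuration errors", {
  expect_error(buildPlan(list(bqsr = "x.recal", knownSites = "s.vcf")),
               "requires bqsrReference")
  expect_error(buildPlan(list(bqsr = "x.recal", bqsrReference = "r.fa")),
               "requires knownSites")
  expect_error(buildPlan(list(markOpticalDuplicates = TRUE)),
               "requires markDuplicates")
  expect_error(buildPlan(list(nonsense = 1)), "unknown option")
  expect_error(buildPlan(list(sortingOrder = "sideways")))
})

test_that("filter composition is short-circuiting conjunction", {
  sam <- mkSam(list(mkRecord(qname = "a", flag = 0L, pos = 10L),
                    mkRecord(qname = "b", flag = 0x4L, rname = "*", pos = 0L,
                             cigar = "*", seq = "AAAA", qual = "IIII"),
                    mkRecord(qname = "c", flag = 0x400L, pos = 20L)))
  seen <- integer(0)
  spy <- samFilter("spy", function(header) list(
    header = header,
    recordFn = function(aln) {
      seen <<- c(seen, nrow(aln))
      list(keep = rep(TRUE, nrow(aln)), aln = aln)
    }))
  # compose([]) keeps everything
  idf <- composeFilters(list())$headerFn(samHeader(sam))
  expect_true(all(idf$recordFn(alignments(sam))$keep))
  # compose([f]) behaves like f
  f1 <- composeFilters(list(filterUnmapped()))$headerFn(samHeader(sam))
  expect_equal(f1$recordFn(alignments(sam))$keep, c(TRUE, FALSE, TRUE))
  # conjunction + short-circuit: spy placed after the filters sees only
  # records both of them kept
  fg <- composeFilters(list(filterUnmapped(), filterRemoveDuplicates(), spy))
  st <- fg$headerFn(samHeader(sam))
  res <- st$recordFn(alignments(sam))
  expect_equal(res$keep, c(TRUE, FALSE, FALSE))
  expect_equal(seen, 1L)
})

test_that("empty plans copy input through, with record conservation accounting", {
  sim <- simReads(simReference(seed = 14), nPairs = 40L, seed = 14)
  inp <- withr::local_tempfile(fileext = ".sam")
  out <- withr::local_tempfile(fileext = ".sam")
  writeSam(sim$sam, inp)
  rep <- runPipeline(buildPlan(list(noPg = TRUE)), inp, out)
  expect_identical(readLines(out), readLines(inp))
  expect_equal(rep$recordsWritten, rep$recordsRead - sum(rep$removed))
  # default run appends exactly one @PG line and nothing else changes
  rep2 <- runPipeline(buildPlan(list()), inp, out)
  l <- readLines(out)
  expect_equal(sum(startsWith(l, "@PG")), 1L)
  expect_identical(l[!startsWith(l, "@PG")], readLines(inp))
})

test_that("unmapped filtering is counted in the run report", {
  sam <- mkSam(c(lapply(1:3, function(i) mkRecord(qname = paste0("m", i))),
                 lapply(1:2, function(i)
                   mkRecord(qname = paste0("u", i), flag = 0x4L, rname = "*",
                            pos = 0L, cigar = "*", seq = "AA", qual = "II"))))
  inp <- withr::local_tempfile(fileext = ".sam")
  writeSam(sam, inp)
  rep <- runPipeline(buildPlan(list(filterUnmappedReads = TRUE)), inp)
  expect_equal(rep$recordsRead, 5L)
  expect_equal(unname(rep$removed["filter-unmapped"]), 2L)
  expect_equal(rep$recordsWritten, 3L)
})

test_that("the merged pipeline equals chaining the steps through temp files", {
  ref <- simReference(seed = 15)
  sim <- simReads(ref, nPairs = 70L, seed = 15)
  td <- withr::local_tempdir()
  inp <- file.path(td, "in.sam"); writeSam(sim$sam, inp)
  fa <- file.path(td, "ref.fa")
  simReference(seed = 15, fasta = fa)
  vcf <- file.path(td, "sites.vcf"); writeLines(sim$vcf, vcf)

  chain <- function(steps) {
    cur <- readSam(inp)
    recal <- NULL
    if ("sort" %in% steps) {
      cur <- sortCoordinate(cur)
      p <- file.path(td, "step1.sam"); writeSam(cur, p); cur <- readSam(p)
    }
    if ("markdup" %in% steps) {
      cur <- markDuplicates(cur, deterministic = TRUE)$sam
      p <- file.path(td, "step2.sam"); writeSam(cur, p); cur <- readSam(p)
    }
    if ("bqsr" %in% steps) {
      tab <- bqsrTabulate(cur, loadReference(fa), loadKnownSites(vcf))
      recal <- computeDeltas(tab)
      writeRecalTable(recal, file.path(td, "chain.recal"))
      recal <- readRecalTable(file.path(td, "chain.recal"))
      cur <- applyBqsr(cur, recal)
      p <- file.path(td, "step3.sam"); writeSam(cur, p); cur <- readSam(p)
    }
    cur
  }
  combos <- list(c("sort"), c("markdup"), c("sort", "markdup"),
                 c("sort", "markdup", "bqsr"), c("bqsr"))
  for (steps in combos) {
    opts <- list(noPg = TRUE, deterministic = TRUE)
    if ("sort" %in% steps) opts$sortingOrder <- "coordinate"
    if ("markdup" %in% steps) opts$markDuplicates <- TRUE
    if ("bqsr" %in% steps) {
      opts$bqsr <- file.path(td, "merged.recal")
      opts$knownSites <- vcf; opts$bqsrReference <- fa
    }
    out <- file.path(td, "merged.sam")
    runPipeline(buildPlan(opts), inp, out)
    expect_identical(readLines(out), samLines(chain(steps)),
                     info = paste(steps, collapse = "+"))
    if ("bqsr" %in% steps)
      expect_identical(readLines(file.path(td, "merged.recal")),
                       readLines(file.path(td, "chain.recal")),
                       info = paste(steps, collapse = "+"))
  }
})

test_that("worker sharding never changes results", {
  sim <- simReads(simReference(seed = 16), nPairs = 50L, seed = 16)
  inp <- withr::local_tempfile(fileext = ".sam")
  writeSam(sim$sam, inp)
  outs <- lapply(c(1L, 2L, 5L, 13L), function(w) {
    out <- tempfile(fileext = ".sam")
    runPipeline(buildPlan(list(filterUnmappedReads = TRUE,
                               removeDuplicates = TRUE,
                               markDuplicates = TRUE,
                               deterministic = TRUE, workers = w)), inp, out)
    readLines(out)
  })
  for (i in 2:4) expect_identical(outs[[i]], outs[[1L]])
})
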