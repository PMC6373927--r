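# The three-phase, single-pass execution core.
#
# Phase 1 applies per-record filters while the input is read; phase 2 runs
# whole-set operations (sort, duplicate marking, recalibration tabulation)
# consecutively over the in-memory file; phase 3 applies output-time
# filters while writing. The input is read exactly once regardless of how
# many steps are requested. Filters obey an order-independence contract
# (no per-record decision depends on a neighbouring record), which is what
# allows merging them into one traversal and applying them to record
# shards in any partition; the engine exploits it by splitting phase-1/3
# filtering across a configurable number of worker shards and recombining
# deterministically.

.defaultOptions <- function() list(
  filterUnmappedReads = FALSE,
  targetRegions = NULL,
  sortingOrder = "keep",
  markDuplicates = FALSE,
  markOpticalDuplicates = FALSE,
  opticalPixelDistance = 100L,
  metricsFile = NULL,
  removeDuplicates = FALSE,
  bqsr = NULL,
  knownSites = NULL,
  bqsrReference = NULL,
  quantizeLevels = NULL,
  preserveBelow = 6L,
  contextSize = 2L,
  sigma = 0.5,
  deterministic = FALSE,
  noPg = FALSE,
  workers = 1L)

#' Build a pipeline plan from options
#'
#' Canonicalizes an option set into the fixed three-phase stage order:
#' phase 1 = region filter, unmapped filter (and header rewrites); phase 2
#' = sort, duplicate marking (with optional optical marking), BQSR
#' tabulation; phase 3 = BQSR application, remove-duplicates filter,
#' metrics emission. Construction is a pure function of the option
#' values, so any two orderings of the same options yield identical plans
#' ("the order in which steps are specified is irrelevant"). Recalibration
#' tabulation is placed after duplicate marking because it must see the
#' duplicate flags.
#'
#' @param options named list; see Details for keys. Unknown keys are an
#'   error. Recognized keys and defaults: filterUnmappedReads (FALSE),
#'   targetRegions (BED path), sortingOrder ("keep"/"coordinate"/
#'   "queryname"), markDuplicates (FALSE), markOpticalDuplicates (FALSE),
#'   opticalPixelDistance (100), metricsFile (path), removeDuplicates
#'   (FALSE), bqsr (recal output path or TRUE), knownSites (path),
#'   bqsrReference (path), quantizeLevels, preserveBelow (6), contextSize
#'   (2), sigma (0.5), deterministic (FALSE), noPg (FALSE), workers (1).
#' @return a [PipelinePlan-class].
#' @export
buildPlan <- function(options = list()) {
  defaults <- .defaultOptions()
  unknown <- setdiff(names(options), names(defaults))
  if (length(unknown))
    stop("unknown option(s): ", paste(unknown, collapse = ", "))
  opts <- defaults
  opts[names(options)] <- options
  opts$sortingOrder <- match.arg(opts$sortingOrder,
                                 c("keep", "coordinate", "queryname"))
  if (!is.null(opts$bqsr) && !isFALSE(opts$bqsr)) {
    if (is.null(opts$bqsrReference))
      stop("configuration error: bqsr requires bqsrReference")
    if (is.null(opts$knownSites))
      stop("configuration error: bqsr requires knownSites")
  } else opts$bqsr <- NULL
  if (isTRUE(opts$markOpticalDuplicates) && !isTRUE(opts$markDuplicates))
    stop("configuration error: markOpticalDuplicates requires markDuplicates")
  opts <- opts[sort(names(opts))]          # canonical key order
  phase1 <- c(if (!is.null(opts$targetRegions)) "filter-regions",
              if (isTRUE(opts$filterUnmappedReads)) "filter-unmapped")
  phase2 <- c(if (opts$sortingOrder != "keep") "sort",
              if (isTRUE(opts$markDuplicates)) "markDuplicates",
              if (!is.null(opts$bqsr)) "bqsrTabulate")
  phase3 <- c(if (!is.null(opts$bqsr)) "bqsrApply",
              if (isTRUE(opts$removeDuplicates)) "remove-duplicates",
              if (!is.null(opts$metricsFile)) "metrics")
  new("PipelinePlan",
      phase1 = as.character(phase1), phase2 = as.character(phase2),
      phase3 = as.character(phase3), options = opts)
}

#' Compose per-record filters
#'
#' Merges a list of filters into one: header stages are applied left to
#' right; the composed per-record stage short-circuits, so a record removed
#' by an earlier filter is never shown to a later one. \code{compose([])}
#' is the keep-all identity.
#'
#' @param filters list of "samFilter" objects.
#' @return a single "samFilter".
#' @export
composeFilters <- function(filters) {
  samFilter("composed", function(header) {
    recordFns <- list()
    for (f in filters) {
      st <- f$headerFn(header)
      header <- st$header
      if (!is.null(st$recordFn)) recordFns[[length(recordFns) + 1L]] <- st$recordFn
    }
    list(header = header, recordFn = function(aln) {
      keep <- rep(TRUE, nrow(aln))
      live <- seq_len(nrow(aln))
      for (fn in recordFns) {
        if (!length(live)) break
        res <- fn(aln[live, , drop = FALSE])
        aln[live, ] <- res$aln
        keep[live[!res$keep]] <- FALSE
        live <- live[res$keep]
      }
      list(keep = keep, aln = aln)
    })
  })
}

# apply one filter's record stage across worker shards; returns
# list(aln, removed). Sharding is contiguous so recombination is a plain
# rbind; results are identical for any worker count by the filter contract.
.applyRecordStage <- function(aln, recordFn, workers = 1L) {
  n <- nrow(aln)
  if (!n) return(list(aln = aln, removed = 0L))
  workers <- max(1L, as.integer(workers))
  bounds <- unique(round(seq(0L, n, length.out = workers + 1L)))
  parts <- lapply(seq_len(length(bounds) - 1L), function(i) {
    shard <- aln[(bounds[i] + 1L):bounds[i + 1L], , drop = FALSE]
    res <- recordFn(shard)
    res$aln[res$keep, , drop = FALSE]
  })
  kept <- do.call(rbind, parts)
  rownames(kept) <- NULL
  list(aln = kept, removed = n - nrow(kept))
}

# instantiate the phase-1/3 filters named in a plan
.instantiateFilter <- function(name, opts, resources) {
  switch(name,
         "filter-regions" = filterRegions(resources$regions),
         "filter-unmapped" = filterUnmapped(),
         "remove-duplicates" = filterRemoveDuplicates(),
         stop("unknown filter: ", name))
}

.loadResources <- function(opts) {
  res <- list()
  if (!is.null(opts$targetRegions))
    res$regions <- if (is(opts$targetRegions, "RegionSet")) opts$targetRegions
                   else readBed(opts$targetRegions)
  if (!is.null(opts$bqsr)) {
    res$reference <- if (is.character(opts$bqsrReference) &&
                         length(opts$bqsrReference) == 1L)
      loadReference(opts$bqsrReference) else opts$bqsrReference
    res$known <- if (is(opts$knownSites, "KnownSites")) opts$knownSites
                 else loadKnownSites(opts$knownSites)
  }
  res
}

# canonical CL string recorded in the @PG line: a pure function of the
# canonical options (no execution-mode marker), so option permutations and
# both execution modes emit identical headers
.planCommandLine <- function(plan) {
  opts <- plan@options
  opts$workers <- NULL        # execution detail, not part of the pipeline
  shown <- opts[!vapply(opts, is.null, logical(1))]
  shown <- shown[!vapply(shown, isFALSE, logical(1))]
  keep <- vapply(shown, function(v) is.character(v) || is.numeric(v) ||
                   isTRUE(v), logical(1))
  shown <- shown[keep]
  paste("samforge",
        paste(vapply(names(shown), function(k) {
          v <- shown[[k]]
          if (isTRUE(v)) paste0("--", k) else paste0("--", k, " ", v)
        }, character(1)), collapse = " "))
}

# run phase 1 on a freshly parsed SamFile: header rewrite + filters.
# Returns list(sam, removed = named counts)
.runPhase1 <- function(sam, plan, resources) {
  opts <- plan@options
  removed <- integer(0)
  header <- sam@header
  aln <- sam@alignments
  for (nm in plan@phase1) {
    f <- .instantiateFilter(nm, opts, resources)
    st <- f$headerFn(header)
    header <- st$header
    if (!is.null(st$recordFn)) {
      res <- .applyRecordStage(aln, st$recordFn, opts$workers)
      aln <- res$aln
      removed[nm] <- res$removed
    }
  }
  sam@header <- header
  sam@alignments <- aln
  list(sam = sam, removed = removed)
}

#' Run a preparation pipeline in memory (filter mode)
#'
#' Executes a [PipelinePlan-class] over a SAM input in one pass: the input
#' is parsed once (phase-1 filters applied as records enter), the whole-set
#' operations run consecutively in memory, and phase-3 filters are applied
#' as records are written. Produces the output SAM (when \code{output} is
#' given), the metrics file and the recalibration report requested by the
#' plan, and returns a run report.
#'
#' @param plan a [PipelinePlan-class] (or option list passed to
#'   [buildPlan()]).
#' @param input SAM path or [samText()].
#' @param output output SAM path, or NULL to skip writing (the processed
#'   [SamFile-class] is in the report either way).
#' @return a "RunReport" list: \code{recordsRead}, \code{removed} (named
#'   per-filter counts), \code{recordsWritten}, \code{sam}, \code{metrics}
#'   (data.frame or NULL), \code{recal} ([RecalTable-class] or NULL),
#'   \code{optical}, \code{warnings}.
#' @export
runPipeline <- function(plan, input, output = NULL) {
  if (!is(plan, "PipelinePlan")) plan <- buildPlan(plan)
  opts <- plan@options
  resources <- .loadResources(opts)
  sam <- readSam(input)
  recordsRead <- nrow(sam@alignments)
  ph1 <- .runPhase1(sam, plan, resources)
  sam <- ph1$sam
  removed <- ph1$removed
  warnings <- character(0)

  # ---- phase 2: whole-set operations ----
  dup <- NULL; optical <- NULL; recal <- NULL
  for (op in plan@phase2) {
    if (op == "sort") {
      sam <- if (opts$sortingOrder == "coordinate") sortCoordinate(sam)
             else sortQueryname(sam)
    } else if (op == "markDuplicates") {
      dup <- markDuplicates(sam, deterministic = opts$deterministic)
      sam <- dup$sam
      warnings <- c(warnings, dup$warnings)
      if (isTRUE(opts$markOpticalDuplicates))
        optical <- markOpticalDuplicates(dup, opts$opticalPixelDistance)
    } else if (op == "bqsrTabulate") {
      tab <- bqsrTabulate(sam, resources$reference, resources$known,
                          contextSize = opts$contextSize)
      recal <- computeDeltas(tab, sigma = opts$sigma)
      if (is.character(opts$bqsr)) writeRecalTable(recal, opts$bqsr)
    }
  }

  # ---- phase 3: output-time steps ----
  metrics <- NULL
  for (st in plan@phase3) {
    if (st == "bqsrApply") {
      sam <- applyBqsr(sam, recal, quantizeLevels = opts$quantizeLevels,
                       preserveBelow = opts$preserveBelow)
    } else if (st == "remove-duplicates") {
      f <- filterRemoveDuplicates()$headerFn(sam@header)
      res <- .applyRecordStage(sam@alignments, f$recordFn, opts$workers)
      sam@alignments <- res$aln
      removed["remove-duplicates"] <- res$removed
    } else if (st == "metrics") {
      if (is.null(dup)) {
        warnings <- c(warnings,
                      "metrics requested without duplicate marking; counts reflect flags only")
        dup <- list(pairs = data.frame(lib = character(0), isDup = logical(0)),
                    fragments = data.frame(lib = character(0), isDup = logical(0)))
      }
      metrics <- computeDuplicationMetrics(dup, sam, optical)
      writeMetrics(metrics, opts$metricsFile)
    }
  }
  if (!isTRUE(opts$noPg))
    sam@header <- appendPg(sam@header, cl = .planCommandLine(plan))
  if (!is.null(output)) writeSam(sam, output)
  structure(list(recordsRead = recordsRead, removed = removed,
                 recordsWritten = nrow(sam@alignments), sam = sam,
                 metrics = metrics, recal = recal, optical = optical,
                 warnings = warnings),
            class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport:", x$recordsRead, "records read,",
      x$recordsWritten, "written\n")
  if (length(x$removed))
    cat("  removed:", paste(names(x$removed), x$removed, sep = "=",
                            collapse = ", "), "\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
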