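# Split-filter-merge mode: scatter the input by genomic region, run the
# pipeline per chunk, merge. Produces byte-identical results to the
# in-memory filter mode (in deterministic mode) by construction: records
# keep their original file ordinals across the scatter, every duplicate
# class is wholly contained in one chunk, and the one cross-chunk rule
# (pairs beat fragments) is honoured by sharing pair-end keys between
# chunks, mirroring the shared hash table of a parallel implementation.

#' Split a SAM file by genomic region
#'
#' Routes every record to exactly one chunk: a record goes to its contig's
#' group when its contig is in the group and, if its mate is mapped, the
#' mate's contig is in the same group; records of pairs spanning two
#' groups (both mates) and unmapped records go to the shared overflow
#' chunk. Same-contig pairs therefore stay whole within one chunk, which
#' keeps pair duplicate classes chunk-local.
#'
#' @param sam a [SamFile-class].
#' @param groups chunk granularity: NULL for one chunk per contig (the
#'   default), an integer number of contiguous contig groups, or an
#'   explicit list of character vectors of contig names.
#' @return list with \code{chunks} (named list of [SamFile-class]) and
#'   \code{overflow} (a [SamFile-class]).
#' @export
splitByRegion <- function(sam, groups = NULL) {
  sq <- sqNames(sam@header)
  if (!length(sq)) stop("split requires @SQ header lines")
  groupList <- if (is.null(groups)) {
    setNames(as.list(sq), sq)
  } else if (is.numeric(groups)) {
    n <- max(1L, min(as.integer(groups), length(sq)))
    split(sq, ceiling(seq_along(sq) * n / length(sq)))
  } else as.list(groups)
  if (is.null(names(groupList)))
    names(groupList) <- vapply(groupList, `[`, character(1), 1L)
  groupOf <- unlist(lapply(names(groupList), function(g)
    setNames(rep(g, length(groupList[[g]])), groupList[[g]])))
  aln <- sam@alignments
  flag <- aln$flag
  mateContig <- ifelse(aln$rnext == "=", aln$rname, aln$rnext)
  mateMapped <- isPaired(flag) & !isMateUnmapped(flag) & mateContig != "*"
  own <- unname(groupOf[aln$rname])
  mateGrp <- unname(groupOf[mateContig])
  dest <- own
  dest[isUnmapped(flag) | is.na(own)] <- NA
  crossing <- mateMapped & (is.na(mateGrp) | mateGrp != own)
  dest[crossing] <- NA                      # spanning pairs -> overflow
  mk <- function(rows) {
    out <- sam
    out@alignments <- aln[rows, , drop = FALSE]
    rownames(out@alignments) <- NULL
    out
  }
  chunks <- lapply(names(groupList), function(g) mk(which(!is.na(dest) & dest == g)))
  names(chunks) <- names(groupList)
  list(chunks = chunks, overflow = mk(which(is.na(dest))))
}

#' Merge processed chunks
#'
#' K-way merge of individually sorted chunks into the final record order.
#' All chunks must carry the same @SQ dictionary (the original order),
#' which becomes the merged header's; a mismatch is an error. Ties at
#' equal coordinates resolve by the records' original file ordinals, so
#' the merged order equals what a whole-file sort would have produced.
#'
#' @param chunks list of [SamFile-class] (including the overflow chunk).
#' @param sortingOrder "coordinate", "queryname" or "keep" (original
#'   order).
#' @return the merged [SamFile-class].
#' @export
mergeChunks <- function(chunks, sortingOrder = "coordinate") {
  stopifnot(length(chunks) >= 1L)
  sqRef <- sqNames(chunks[[1L]]@header)
  for (ch in chunks[-1L])
    if (!identical(sqNames(ch@header), sqRef))
      stop("chunk @SQ dictionaries differ; refusing to merge")
  aln <- do.call(rbind, lapply(chunks, alignments))
  rownames(aln) <- NULL
  o <- switch(sortingOrder,
              coordinate = {
                idx <- match(aln$rname, sqRef)
                order(idx, aln$pos, aln$fileIndex, method = "radix",
                      na.last = TRUE)
              },
              queryname = order(aln$qname, aln$fileIndex, method = "radix"),
              keep = order(aln$fileIndex, method = "radix"))
  out <- chunks[[1L]]
  out@alignments <- aln[o, , drop = FALSE]
  rownames(out@alignments) <- NULL
  out
}

# pair-end keys of a chunk, for the cross-chunk pairs-beat-fragments rule
.pairEndKeys <- function(sam) {
  aln <- sam@alignments
  if (!nrow(aln)) return(character(0))
  flag <- aln$flag
  eligible <- !isUnmapped(flag) & !isSecondary(flag) & !isSupplementary(flag)
  cand <- which(eligible & isPaired(flag) & !isMateUnmapped(flag))
  if (!length(cand)) return(character(0))
  cnt <- table(aln$qname[cand])
  cand <- cand[aln$qname[cand] %in% names(cnt)[cnt == 2L]]
  if (!length(cand)) return(character(0))
  lib <- .recordLibraries(aln, sam@header)
  contigIdx <- match(aln$rname, sqNames(sam@header))
  ucp <- unclippedPosition(aln[cand, , drop = FALSE])
  strand <- ifelse(isReverse(flag[cand]), "R", "F")
  unique(paste(lib[cand], contigIdx[cand], ucp, strand, sep = "|"))
}

#' Run a preparation pipeline in split-filter-merge mode
#'
#' Same contract as [runPipeline()] but executed as scatter/gather:
#' the input is split by genomic region ([splitByRegion()]), phase-1
#' filters, sorting and duplicate marking run per chunk, per-chunk
#' recalibration tables are reduced into one global table before deltas
#' are computed, and recalibrated qualities are applied on the merge pass.
#' In deterministic mode the output SAM, metrics and recalibration files
#' are byte-identical to filter mode.
#'
#' @param plan a [PipelinePlan-class] or option list.
#' @param input SAM path or [samText()].
#' @param output output SAM path or NULL.
#' @param chunkDir directory for the intermediate chunk files; created if
#'   needed, reused if a previous interrupted run left it behind, removed
#'   on success. NULL keeps the scatter purely in memory.
#' @param groups chunk granularity, see [splitByRegion()].
#' @return a "RunReport" list as for [runPipeline()].
#' @export
runSfm <- function(plan, input, output = NULL, chunkDir = NULL,
                   groups = NULL) {
  if (!is(plan, "PipelinePlan")) plan <- buildPlan(plan)
  opts <- plan@options
  resources <- .loadResources(opts)
  sam <- readSam(input)
  recordsRead <- nrow(sam@alignments)
  sp <- splitByRegion(sam, groups)
  parts <- c(sp$chunks, list(.overflow = sp$overflow))
  if (!is.null(chunkDir)) {
    if (dir.exists(chunkDir)) unlink(chunkDir, recursive = TRUE)
    dir.create(chunkDir, recursive = TRUE)
    for (nm in names(parts))
      writeSam(parts[[nm]], file.path(chunkDir, paste0(nm, ".sam")))
  }
  warnings <- character(0)
  removed <- integer(0)
  addRemoved <- function(removed, r) {
    for (nm in names(r)) removed[nm] <- sum(removed[nm], r[nm], na.rm = TRUE)
    removed
  }

  # phase 1 + per-chunk sort
  for (nm in names(parts)) {
    ph1 <- .runPhase1(parts[[nm]], plan, resources)
    parts[[nm]] <- ph1$sam
    removed <- addRemoved(removed, ph1$removed)
    if ("sort" %in% plan@phase2)
      parts[[nm]] <- if (opts$sortingOrder == "coordinate")
        sortCoordinate(parts[[nm]]) else sortQueryname(parts[[nm]])
  }

  # duplicate marking per chunk, sharing pair-end keys across chunks
  dupPairs <- list(); dupFrags <- list(); optical <- NULL
  if ("markDuplicates" %in% plan@phase2) {
    allKeys <- unique(unlist(lapply(parts, .pairEndKeys)))
    optAcc <- numeric(0)
    for (nm in names(parts)) {
      dup <- markDuplicates(parts[[nm]], deterministic = opts$deterministic,
                            externalPairKeys = allKeys)
      parts[[nm]] <- dup$sam
      warnings <- c(warnings, dup$warnings)
      dupPairs[[nm]] <- dup$pairs
      dupFrags[[nm]] <- dup$fragments
      if (isTRUE(opts$markOpticalDuplicates)) {
        oc <- markOpticalDuplicates(dup, opts$opticalPixelDistance)
        for (l in names(oc)) optAcc[l] <- sum(optAcc[l], oc[l], na.rm = TRUE)
      }
    }
    if (isTRUE(opts$markOpticalDuplicates)) optical <- optAcc
  }

  # recalibration: per-chunk tabulation reduced into one table
  recal <- NULL
  if ("bqsrTabulate" %in% plan@phase2) {
    tabs <- lapply(parts, function(ch)
      bqsrTabulate(ch, resources$reference, resources$known,
                   contextSize = opts$contextSize))
    recal <- computeDeltas(mergeRecalTables(tabs), sigma = opts$sigma)
    if (is.character(opts$bqsr)) writeRecalTable(recal, opts$bqsr)
  }

  merged <- mergeChunks(unname(parts), sortingOrder = opts$sortingOrder)

  # phase 3 on the merge pass
  metrics <- NULL
  catDf <- function(lst) {
    lst <- c(lst, list(data.frame(lib = character(0), isDup = logical(0))))
    as.data.frame(data.table::rbindlist(lst, fill = TRUE))
  }
  dupAll <- list(pairs = catDf(dupPairs), fragments = catDf(dupFrags))
  for (st in plan@phase3) {
    if (st == "bqsrApply") {
      merged <- applyBqsr(merged, recal, quantizeLevels = opts$quantizeLevels,
                          preserveBelow = opts$preserveBelow)
    } else if (st == "remove-duplicates") {
      f <- filterRemoveDuplicates()$headerFn(merged@header)
      res <- .applyRecordStage(merged@alignments, f$recordFn, opts$workers)
      merged@alignments <- res$aln
      removed["remove-duplicates"] <- res$removed
    } else if (st == "metrics") {
      metrics <- computeDuplicationMetrics(dupAll, merged, optical)
      writeMetrics(metrics, opts$metricsFile)
    }
  }
  if (!isTRUE(opts$noPg))
    merged@header <- appendPg(merged@header, cl = .planCommandLine(plan))
  if (!is.null(output)) writeSam(merged, output)
  if (!is.null(chunkDir)) unlink(chunkDir, recursive = TRUE)
  structure(list(recordsRead = recordsRead, removed = removed,
                 recordsWritten = nrow(merged@alignments), sam = merged,
                 metrics = metrics, recal = recal, optical = optical,
                 warnings = warnings),
            class = "RunReport")
}
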