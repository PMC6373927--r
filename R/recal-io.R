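# Text serialization of recalibration tables. The dialect is this tool's
# own fixed-format report (GATKReport-inspired): one section per covariate
# level, fixed column order, counts as integers, qualities and deltas to 4
# decimal places. Because the in-memory deltas are already rounded to that
# precision, write -> read is the identity and two runs on identical input
# serialize byte-identically.

.fmt4 <- function(x) sprintf("%.4f", x)
.fmtCount <- function(x) sprintf("%.0f", x)

#' Write a recalibration table report
#'
#' @param table a [RecalTable-class] (with or without deltas).
#' @param path output path or connection.
#' @return invisibly, the path.
#' @seealso [readRecalTable()]
#' @export
writeRecalTable <- function(table, path) {
  p <- table@params
  hasD <- isTRUE(p$hasDeltas)
  out <- c("#:samforge.recal:v1",
           paste0("#:context:", p$context),
           paste0("#:deltas:", if (hasD) "yes" else "no"),
           if (hasD) paste0("#:sigma:", .fmt4(p$sigma)))
  sec <- function(name, df, keyCols, keyFmt) {
    isRG <- name == "ReadGroupTable"
    cols <- c(keyCols, "Observations", "Errors",
              if (isRG) "SumReportedQ",
              if (hasD) c(if (isRG) "EstimatedQ", "EmpiricalQ", "Delta"))
    rows <- character(nrow(df))
    if (nrow(df)) {
      keys <- do.call(cbind, lapply(seq_along(keyCols), function(i)
        keyFmt[[i]](df[[i]])))
      body <- cbind(keys, .fmtCount(df$obs), .fmtCount(df$err))
      if (isRG) body <- cbind(body, .fmtCount(df$sumQ))
      if (hasD) {
        if (isRG) body <- cbind(body, .fmt4(df$estQ))
        body <- cbind(body, .fmt4(df$empQ), .fmt4(df$delta))
      }
      rows <- apply(body, 1L, paste, collapse = "\t")
    }
    c(paste0("## ", name), paste(cols, collapse = "\t"), rows)
  }
  chr <- function(x) x
  int <- function(x) sprintf("%d", as.integer(x))
  out <- c(out,
           sec("ReadGroupTable", table@global, "ReadGroup", list(chr)),
           sec("QualityTable", table@byQ, c("ReadGroup", "ReportedQ"),
               list(chr, int)),
           sec("CycleTable", table@byCycle,
               c("ReadGroup", "ReportedQ", "Cycle"), list(chr, int, int)),
           sec("ContextTable", table@byContext,
               c("ReadGroup", "ReportedQ", "Context"), list(chr, int, chr)))
  writeLines(out, path)
  invisible(path)
}

#' Read a recalibration table report
#'
#' Inverse of [writeRecalTable()]: \code{readRecalTable(writeRecalTable(t))}
#' equals \code{t}.
#'
#' @param path report path.
#' @return a [RecalTable-class].
#' @export
readRecalTable <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "#:samforge.recal:v1")
    stop("recal parse error: missing format header")
  meta <- lines[startsWith(lines, "#:")]
  getMeta <- function(key) {
    hit <- meta[startsWith(meta, paste0("#:", key, ":"))]
    if (!length(hit)) NA_character_ else sub(paste0("^#:", key, ":"), "", hit[1L])
  }
  hasD <- identical(getMeta("deltas"), "yes")
  secStarts <- which(startsWith(lines, "## "))
  if (!length(secStarts)) stop("recal parse error: no sections")
  sections <- list()
  for (i in seq_along(secStarts)) {
    s <- secStarts[i]
    e <- if (i < length(secStarts)) secStarts[i + 1L] - 1L else length(lines)
    name <- sub("^## ", "", lines[s])
    if (s + 1L > e) stop("recal parse error: malformed section header")
    body <- lines[(s + 2L):e][seq_len(max(0L, e - s - 1L))]
    cols <- strsplit(lines[s + 1L], "\t", fixed = TRUE)[[1L]]
    df <- if (length(body)) {
      m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
      as.data.frame(m, stringsAsFactors = FALSE)
    } else {
      as.data.frame(matrix(character(0), ncol = length(cols)))
    }
    names(df) <- cols
    sections[[name]] <- df
  }
  need <- c("ReadGroupTable", "QualityTable", "CycleTable", "ContextTable")
  if (!all(need %in% names(sections)))
    stop("recal parse error: missing section(s): ",
         paste(setdiff(need, names(sections)), collapse = ", "))
  num <- function(x) as.numeric(x)
  g <- sections$ReadGroupTable
  global <- data.frame(rg = as.character(g$ReadGroup),
                       obs = num(g$Observations), err = num(g$Errors),
                       sumQ = num(g$SumReportedQ), stringsAsFactors = FALSE)
  bq <- sections$QualityTable
  byQ <- data.frame(rg = as.character(bq$ReadGroup),
                    q = as.integer(bq$ReportedQ),
                    obs = num(bq$Observations), err = num(bq$Errors),
                    stringsAsFactors = FALSE)
  bc <- sections$CycleTable
  byCycle <- data.frame(rg = as.character(bc$ReadGroup),
                        q = as.integer(bc$ReportedQ),
                        cycle = as.integer(bc$Cycle),
                        obs = num(bc$Observations), err = num(bc$Errors),
                        stringsAsFactors = FALSE)
  bk <- sections$ContextTable
  byContext <- data.frame(rg = as.character(bk$ReadGroup),
                          q = as.integer(bk$ReportedQ),
                          context = as.character(bk$Context),
                          obs = num(bk$Observations), err = num(bk$Errors),
                          stringsAsFactors = FALSE)
  if (hasD) {
    global$empQ <- num(g$EmpiricalQ); global$delta <- num(g$Delta)
    global$estQ <- num(g$EstimatedQ)
    byQ$empQ <- num(bq$EmpiricalQ); byQ$delta <- num(bq$Delta)
    byCycle$empQ <- num(bc$EmpiricalQ); byCycle$delta <- num(bc$Delta)
    byContext$empQ <- num(bk$EmpiricalQ); byContext$delta <- num(bk$Delta)
  }
  params <- list(context = as.integer(getMeta("context")), hasDeltas = hasD)
  if (hasD) params$sigma <- as.numeric(getMeta("sigma"))
  new("RecalTable", global = global, byQ = byQ, byCycle = byCycle,
      byContext = byContext, params = params)
}
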