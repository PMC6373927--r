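# SAM text reading/writing and flag/CIGAR primitives.
#
# The parser is lossless: mandatory fields are typed, optional tag fields
# are kept as the verbatim tab-joined string so the writer reproduces the
# input byte for byte. All functions on flags and CIGAR strings are
# vectorized; per-record wrappers exist where the single-record semantics
# matter (e.g. unclippedPosition()).

.emptyAlignments <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext = integer(0), tlen = integer(0),
             seq = character(0), qual = character(0), tags = character(0),
             fileIndex = integer(0), stringsAsFactors = FALSE)
}

CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"
TAG_RE <- "^[A-Za-z][A-Za-z0-9]:[AifZHB]:"

#' Read a SAM file
#'
#' Parses SAM v1 text into a [SamFile-class]. Header lines (starting with
#' "@") must precede alignment lines. Every alignment line must have at
#' least the 11 mandatory tab-separated fields; optional fields must follow
#' the \code{XX:T:value} tag grammar and CIGAR strings may only use the
#' operators \code{MIDNSHP=X}. Violations raise an error naming the
#' offending line. Each record is assigned a \code{fileIndex} equal to its
#' 0-based ordinal among the alignment lines.
#'
#' @param path path to a SAM file, or a character vector of SAM lines
#'   (class "samText", see [samText()]).
#' @return a [SamFile-class].
#' @seealso [writeSam()]
#' @examples
#' sam <- samText(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
#'                  "r1\t0\tchr1\t100\t60\t4M\t*\t0\t0\tACGT\tIIII"))
#' readSam(sam)
#' @export
readSam <- function(path) {
  lines <- if (inherits(path, "samText")) unclass(path) else readLines(path)
  isHeader <- startsWith(lines, "@")
  nHead <- if (all(isHeader)) length(lines) else which(!isHeader)[1L] - 1L
  body <- if (nHead == 0L) lines else lines[-seq_len(nHead)]
  if (any(startsWith(body, "@")))
    stop("header line found after alignment lines")
  header <- new("SamHeader", lines = lines[seq_len(nHead)])
  body <- body[nzchar(body)]
  if (!length(body))
    return(new("SamFile", header = header, alignments = .emptyAlignments()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1L]
    stop(sprintf("SAM parse error at alignment line %d: %d fields (11 required)",
                 bad, nf[bad]))
  }
  grab <- function(i) vapply(fields, `[[`, character(1), i)
  tags <- vapply(fields, function(f)
    if (length(f) > 11L) paste(f[-seq_len(11L)], collapse = "\t") else "",
    character(1))
  aln <- data.frame(
    qname = grab(1L), flag = as.integer(grab(2L)), rname = grab(3L),
    pos = as.integer(grab(4L)), mapq = as.integer(grab(5L)),
    cigar = grab(6L), rnext = grab(7L), pnext = as.integer(grab(8L)),
    tlen = as.integer(grab(9L)), seq = grab(10L), qual = grab(11L),
    tags = tags, fileIndex = seq_along(fields) - 1L,
    stringsAsFactors = FALSE)
  badCigar <- aln$cigar != "*" & !grepl(CIGAR_RE, aln$cigar)
  if (any(badCigar))
    stop(sprintf("SAM parse error at alignment line %d: malformed CIGAR '%s'",
                 which(badCigar)[1L], aln$cigar[which(badCigar)[1L]]))
  hasTags <- nzchar(tags)
  if (any(hasTags)) {
    tagFields <- strsplit(tags[hasTags], "\t", fixed = TRUE)
    ok <- vapply(tagFields, function(tf) all(grepl(TAG_RE, tf)), logical(1))
    if (!all(ok)) {
      bad <- which(hasTags)[which(!ok)[1L]]
      stop(sprintf("SAM parse error at alignment line %d: malformed tag field", bad))
    }
  }
  new("SamFile", header = header, alignments = aln)
}

#' Mark a character vector as in-memory SAM text
#'
#' Convenience wrapper so [readSam()] and the pipeline runners can accept
#' SAM content directly instead of a file path.
#'
#' @param lines character vector of SAM lines.
#' @return the same vector with class "samText".
#' @export
samText <- function(lines) structure(as.character(lines), class = "samText")

#' Format a SamFile as SAM text lines
#' @param sam a [SamFile-class].
#' @return character vector: header lines then one line per record.
#' @export
samLines <- function(sam) {
  aln <- sam@alignments
  if (!nrow(aln)) return(sam@header@lines)
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
                aln$rnext, aln$pnext, aln$tlen, aln$seq, aln$qual, sep = "\t")
  hasTags <- nzchar(aln$tags)
  body[hasTags] <- paste(body[hasTags], aln$tags[hasTags], sep = "\t")
  c(sam@header@lines, body)
}

#' Write a SamFile as SAM text
#'
#' Inverse of [readSam()]: \code{readSam(writeSam(x, path))} reproduces
#' \code{x} field for field, and writing a freshly parsed file reproduces
#' the input bytes (tag order is preserved verbatim).
#'
#' @param sam a [SamFile-class].
#' @param path output file path or connection.
#' @return invisibly, the path.
#' @export
writeSam <- function(sam, path) {
  writeLines(samLines(sam), path)
  invisible(path)
}

# ---- flag predicates (one documented SAM flag bit each) ----

#' SAM flag predicates
#'
#' Vectorized tests of the documented SAM flag bits: paired (0x1), unmapped
#' (0x4), mate unmapped (0x8), reverse strand (0x10), first of pair (0x40),
#' secondary (0x100), duplicate (0x400), supplementary (0x800).
#'
#' @param flag integer vector of SAM flags.
#' @return logical vector.
#' @name flagPredicates
NULL

#' @rdname flagPredicates
#' @export
isPaired <- function(flag) bitwAnd(flag, 0x1L) != 0L
#' @rdname flagPredicates
#' @export
isUnmapped <- function(flag) bitwAnd(flag, 0x4L) != 0L
#' @rdname flagPredicates
#' @export
isMateUnmapped <- function(flag) bitwAnd(flag, 0x8L) != 0L
#' @rdname flagPredicates
#' @export
isReverse <- function(flag) bitwAnd(flag, 0x10L) != 0L
#' @rdname flagPredicates
#' @export
isFirstOfPair <- function(flag) bitwAnd(flag, 0x40L) != 0L
#' @rdname flagPredicates
#' @export
isSecondary <- function(flag) bitwAnd(flag, 0x100L) != 0L
#' @rdname flagPredicates
#' @export
isDuplicate <- function(flag) bitwAnd(flag, 0x400L) != 0L
#' @rdname flagPredicates
#' @export
isSupplementary <- function(flag) bitwAnd(flag, 0x800L) != 0L

# ---- CIGAR helpers (vectorized over cigar strings) ----

.cigarTokens <- function(cigars) {
  # list of (lengths, ops) per cigar; "*" -> zero-length
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigars)
  toks <- regmatches(cigars, m)
  lapply(toks, function(tk) {
    if (!length(tk) || identical(tk, character(0)))
      return(list(len = integer(0), op = character(0)))
    n <- nchar(tk)
    list(len = as.integer(substr(tk, 1L, n - 1L)), op = substr(tk, n, n))
  })
}

#' Reference span length of CIGAR strings
#'
#' Number of reference bases consumed: the sum of M/D/N/=/X operator
#' lengths. "*" yields 0.
#'
#' @param cigars character vector of CIGAR strings.
#' @return integer vector.
#' @export
cigarRefLength <- function(cigars) {
  vapply(.cigarTokens(cigars), function(tk)
    sum(tk$len[tk$op %in% c("M", "D", "N", "=", "X")]), integer(1))
}

# leading/trailing soft+hard clip lengths
.clipLengths <- function(cigars) {
  toks <- .cigarTokens(cigars)
  lead <- vapply(toks, function(tk) {
    clip <- tk$op %in% c("S", "H")
    k <- which(!clip)
    if (!length(k)) return(sum(tk$len))
    sum(tk$len[seq_len(k[1L] - 1L)])
  }, integer(1))
  trail <- vapply(toks, function(tk) {
    clip <- tk$op %in% c("S", "H")
    k <- which(!clip)
    if (!length(k)) return(0L)
    last <- k[length(k)]
    if (last == length(tk$op)) 0L else sum(tk$len[(last + 1L):length(tk$len)])
  }, integer(1))
  list(lead = lead, trail = trail)
}

# ---- tag access ----

#' Extract an optional tag value from records
#'
#' @param tags character vector of verbatim tag strings (the \code{tags}
#'   column of an alignment table).
#' @param tag two-character tag name, e.g. "RG".
#' @return character vector of values (NA where absent).
#' @export
getTagValue <- function(tags, tag) {
  pat <- paste0("(?:^|\t)", tag, ":[AifZHB]:([^\t]*)")
  m <- regexec(pat, tags)
  vapply(regmatches(tags, m), function(g)
    if (length(g) == 2L) g[2L] else NA_character_, character(1))
}

# ---- header accessors ----

.headerField <- function(lines, recType, key) {
  sel <- startsWith(lines, recType)
  vapply(lines[sel], function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]][-1L]
    hit <- f[startsWith(f, paste0(key, ":"))]
    if (length(hit)) substring(hit[1L], 4L) else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

.rgField <- function(header, key) .headerField(header@lines, "@RG", key)

#' Header accessors
#'
#' \code{sqNames}/\code{sqLengths} read the \code{@SQ} dictionary (file
#' order, which defines the coordinate-sort reference order);
#' \code{sortOrder} reads the \code{@HD SO} field ("unknown" when absent);
#' \code{rgLibraries} maps \code{@RG} IDs to \code{LB} values.
#'
#' @param header a [SamHeader-class].
#' @return see details.
#' @name headerAccessors
NULL

#' @rdname headerAccessors
#' @export
sqNames <- function(header) .headerField(header@lines, "@SQ", "SN")

#' @rdname headerAccessors
#' @export
sqLengths <- function(header) {
  setNames(as.integer(.headerField(header@lines, "@SQ", "LN")), sqNames(header))
}

#' @rdname headerAccessors
#' @export
sortOrder <- function(header) {
  so <- .headerField(header@lines, "@HD", "SO")
  if (length(so) && !is.na(so[1L])) so[1L] else "unknown"
}

#' @rdname headerAccessors
#' @export
rgLibraries <- function(header) {
  ids <- .rgField(header, "ID")
  lbs <- .rgField(header, "LB")
  setNames(lbs, ids)
}

#' @rdname headerAccessors
#' @export
rgPlatformUnits <- function(header) {
  ids <- .rgField(header, "ID")
  setNames(.rgField(header, "PU"), ids)
}

#' Set the header sort order
#'
#' Rewrites (or creates) the \code{@HD} line's \code{SO} field.
#'
#' @param header a [SamHeader-class].
#' @param so one of "unknown", "unsorted", "queryname", "coordinate".
#' @return the modified header.
#' @export
setSortOrder <- function(header, so) {
  so <- match.arg(so, c("unknown", "unsorted", "queryname", "coordinate"))
  lines <- header@lines
  hd <- which(startsWith(lines, "@HD"))
  if (length(hd)) {
    f <- strsplit(lines[hd[1L]], "\t", fixed = TRUE)[[1L]]
    isSO <- startsWith(f, "SO:")
    if (any(isSO)) f[isSO] <- paste0("SO:", so)
    else f <- c(f, paste0("SO:", so))
    lines[hd[1L]] <- paste(f, collapse = "\t")
  } else {
    lines <- c(paste0("@HD\tVN:1.6\tSO:", so), lines)
  }
  new("SamHeader", lines = lines)
}

#' Append a @PG line to a header
#'
#' The engine records its own program entry by default; suppress with the
#' no-PG option when byte-exact comparison against another tool's output is
#' wanted.
#'
#' @param header a [SamHeader-class].
#' @param id,pn,vn,cl program record fields (ID, PN, VN, CL).
#' @return the modified header.
#' @export
appendPg <- function(header, id = "samforge", pn = "samforge",
                     vn = "0.1.0", cl = "") {
  ids <- .headerField(header@lines, "@PG", "ID")
  ids <- ids[!is.na(ids)]
  base <- id; k <- 1L
  while (id %in% ids) { id <- paste0(base, ".", k); k <- k + 1L }
  line <- paste0("@PG\tID:", id, "\tPN:", pn, "\tVN:", vn,
                 if (nzchar(cl)) paste0("\tCL:", cl) else "")
  new("SamHeader", lines = c(header@lines, line))
}
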