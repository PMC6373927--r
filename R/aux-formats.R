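# Readers for FASTA / VCF / BED and the fast internal archive formats that
# play the role of a pre-digested reference and known-sites store, so that
# repeated pipeline runs do not re-parse the text formats.

#' Read a reference genome from FASTA
#'
#' Loads a FASTA file into a reference map: a named character vector,
#' contig name -> uppercase base string. Only the first whitespace-separated
#' token of each FASTA description is used as the contig name, matching SAM
#' \code{@SQ SN} conventions.
#'
#' @param path FASTA file path.
#' @return named character vector (class "ReferenceMap" semantics: plain
#'   vector, names are contigs).
#' @export
readFastaRef <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm))
    stop("duplicate contig name in FASTA: ", nm[duplicated(nm)][1L])
  setNames(toupper(as.character(dss)), nm)
}

.archiveWrite <- function(kind, data, path) {
  saveRDS(list(format = "samforge-archive", version = 1L, kind = kind,
               data = data), path)
  invisible(path)
}

.archiveRead <- function(kind, path) {
  x <- readRDS(path)
  if (!identical(x$format, "samforge-archive") || !identical(x$kind, kind))
    stop("not a samforge ", kind, " archive: ", path)
  if (x$version != 1L) stop("unsupported archive version: ", x$version)
  x$data
}

#' Convert FASTA to the internal reference archive
#'
#' One-off conversion so pipelines can reload the reference without
#' re-parsing FASTA line structure. \code{loadReference} reads either an
#' archive produced here or falls back to FASTA when given one.
#'
#' @param fasta input FASTA path.
#' @param out output archive path.
#' @return invisibly, the loaded reference map.
#' @export
convertFasta <- function(fasta, out) {
  ref <- readFastaRef(fasta)
  .archiveWrite("reference", ref, out)
  invisible(ref)
}

#' @rdname convertFasta
#' @param path archive (or FASTA) path.
#' @export
loadReference <- function(path) {
  ok <- tryCatch(.archiveRead("reference", path), error = function(e) NULL)
  if (!is.null(ok)) return(ok)
  readFastaRef(path)
}

#' Read known polymorphic sites from VCF
#'
#' Parses VCF v4 text into a [KnownSites-class]. Only CHROM, POS, REF and
#' ALT are consumed: each data line contributes one site at POS whose span
#' is the REF length (so a deletion allele masks its whole footprint);
#' multi-allelic lines contribute the longest REF span. INFO and genotype
#' columns are ignored. Sites are sorted and de-duplicated per contig
#' (keeping the longest span at a position).
#'
#' @param path VCF file path, or character vector of VCF lines.
#' @param posOnly mask only the POS coordinate instead of the full REF
#'   span (the alternative masking policy; default FALSE).
#' @return a [KnownSites-class].
#' @export
readVcfSites <- function(path, posOnly = FALSE) {
  lines <- if (length(path) > 1L || grepl("[\t\n]", path[1L]))
    unlist(strsplit(path, "\n", fixed = TRUE)) else readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(new("KnownSites", sites = data.frame(
      contig = character(0), pos = integer(0), span = integer(0))))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L))
    stop(sprintf("VCF parse error at data line %d: %d fields (8 required)",
                 which(nf < 8L)[1L], nf[which(nf < 8L)[1L]]))
  contig <- vapply(fields, `[[`, character(1), 1L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 2L))
  span <- if (posOnly) rep(1L, length(pos))
          else nchar(vapply(fields, `[[`, character(1), 4L))
  df <- data.frame(contig = contig, pos = pos, span = as.integer(span),
                   stringsAsFactors = FALSE)
  df <- df[order(df$contig, df$pos, -df$span, method = "radix"), , drop = FALSE]
  df <- df[!duplicated(df[c("contig", "pos")]), , drop = FALSE]
  rownames(df) <- NULL
  new("KnownSites", sites = df)
}

#' Convert VCF to the internal known-sites archive
#'
#' @param vcf input VCF path.
#' @param out output archive path.
#' @return invisibly, the loaded [KnownSites-class].
#' @export
convertVcf <- function(vcf, out) {
  ks <- readVcfSites(vcf)
  .archiveWrite("sites", ks@sites, out)
  invisible(ks)
}

#' @rdname convertVcf
#' @param path archive (or VCF) path.
#' @export
loadKnownSites <- function(path) {
  ok <- tryCatch(.archiveRead("sites", path), error = function(e) NULL)
  if (!is.null(ok)) return(new("KnownSites", sites = ok))
  readVcfSites(path)
}

# expand a KnownSites object into per-contig masked position vectors
.sitesMask <- function(known) {
  s <- known@sites
  if (!nrow(s)) return(list())
  expanded <- data.frame(
    contig = rep(s$contig, s$span),
    pos = unlist(lapply(seq_len(nrow(s)), function(i)
      s$pos[i]:(s$pos[i] + s$span[i] - 1L))))
  split(expanded$pos, expanded$contig)
}

#' Read target regions from a BED file
#'
#' Parses BED3+ text into a [RegionSet-class]. BED intervals are 0-based
#' half-open; they are converted to 1-based closed internally and merged per
#' contig (overlapping or adjacent intervals become one). Columns beyond the
#' third are ignored. An interval with end <= start is an error naming the
#' line.
#'
#' @param path BED file path, or character vector of BED lines.
#' @return a [RegionSet-class].
#' @export
readBed <- function(path) {
  lines <- if (length(path) > 1L || grepl("[\t\n]", path[1L]))
    unlist(strsplit(path, "\n", fixed = TRUE)) else readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(new("RegionSet", regions = list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 which(nf < 3L)[1L]))
  contig <- vapply(fields, `[[`, character(1), 1L)
  start0 <- as.integer(vapply(fields, `[[`, character(1), 2L))
  end0 <- as.integer(vapply(fields, `[[`, character(1), 3L))
  bad <- end0 <= start0
  if (any(bad))
    stop(sprintf("BED parse error at line %d: end <= start", which(bad)[1L]))
  # BED [start0, end0) -> 1-based closed [start0+1, end0]
  byContig <- split(seq_along(contig), contig)
  regions <- lapply(byContig, function(i)
    IRanges::reduce(IRanges::IRanges(start = start0[i] + 1L, end = end0[i])))
  new("RegionSet", regions = regions)
}

#' Test positions for region membership
#'
#' @param regions a [RegionSet-class].
#' @param contig character vector of contig names.
#' @param start,end 1-based closed query spans (vectors recycled to common
#'   length).
#' @return logical vector: does each span overlap any interval of its
#'   contig? Contigs absent from the set yield FALSE.
#' @export
regionOverlaps <- function(regions, contig, start, end = start) {
  n <- max(length(contig), length(start), length(end))
  contig <- rep_len(contig, n); start <- rep_len(start, n); end <- rep_len(end, n)
  out <- logical(n)
  for (ct in unique(contig)) {
    ir <- regions@regions[[ct]]
    sel <- contig == ct
    if (is.null(ir)) next
    q <- IRanges::IRanges(start = start[sel], end = end[sel])
    out[sel] <- IRanges::overlapsAny(q, ir)
  }
  out
}
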