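# Interval plumbing: peak sets are GRanges with unique names as peak ids.
# Internally coordinates are the usual Bioconductor 1-based closed intervals;
# BED files are 0-based half-open and are shifted exactly once at the I/O
# boundary, so round-trips never move a coordinate.

#' Construct a peak set
#'
#' A peak set is a [GenomicRanges::GRanges] whose names are unique peak ids;
#' this helper builds one from 0-based half-open coordinates (the BED
#' convention used by all tabular inputs of the package).
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates (`start < end`).
#' @param id unique peak ids; `peak_1 ...` when omitted.
#' @param strand `+`, `-` or `*`; `*` when omitted.
#' @param score optional numeric score.
#' @return a named `GRanges`.
#' @examples
#' peakSet("chr1", c(100, 300), c(200, 400))
#' @export
peakSet <- function(chrom, start, end, id = NULL, strand = NULL,
                    score = NULL) {
  if (any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  n <- length(start)
  if (is.null(id)) id <- paste0("peak_", seq_len(n))
  if (anyDuplicated(id)) stop("peak ids must be unique")
  if (is.null(strand)) strand <- rep("*", n)
  gr <- GRanges(chrom, IRanges(start + 1L, end), strand = strand)
  names(gr) <- id
  if (!is.null(score)) mcols(gr)$score <- score
  gr
}

.checkPeakSet <- function(x, what = "peaks") {
  if (!is(x, "GRanges"))
    stop(sprintf("'%s' must be a GRanges peak set", what))
  if (length(x) > 0 && (is.null(names(x)) || anyDuplicated(names(x))))
    stop(sprintf("'%s' must carry unique peak ids as names", what))
  invisible(x)
}

#' Read a BED file into a peak set
#'
#' Accepts 3- to 6-column BED (chrom, start, end, name, score, strand).
#' Coordinates are 0-based half-open in the file and stored as 1-based
#' closed `GRanges`; no coordinate is ever shifted beyond that single,
#' exact conversion.  Three-column files receive auto-assigned ids
#' `peak_1 ...`.
#'
#' @param path BED file path.
#' @return a named `GRanges` (mcols: `score` when the file has >= 5
#'   columns).
#' @seealso [writeBed()]
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(GRanges())
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": non-numeric coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("malformed BED line ", bad[1L],
         ": interval must satisfy 0 <= start < end")
  id <- if (all(nf >= 4L)) vapply(fields, `[`, "", 4L)
        else paste0("peak_", seq_along(fields))
  if (anyDuplicated(id))
    stop("duplicate peak ids in ", path, ": ",
         id[anyDuplicated(id)][1L])
  score <- if (all(nf >= 5L))
    suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L))) else NULL
  strand <- if (all(nf >= 6L)) vapply(fields, `[`, "", 6L)
            else rep("*", length(fields))
  strand[strand == "."] <- "*"
  peakSet(chrom, start, end, id = id, strand = strand, score = score)
}

#' Write a peak set as 6-column BED
#'
#' @param peaks a named `GRanges` peak set.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readBed()]
#' @export
writeBed <- function(peaks, path) {
  .checkPeakSet(peaks)
  score <- if (!is.null(mcols(peaks)$score)) mcols(peaks)$score
           else rep(0, length(peaks))
  score[is.na(score)] <- 0
  strand <- as.character(strand(peaks))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = if (length(peaks)) names(peaks) else character(),
                   score = score, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlapping peak pairs between two peak sets
#'
#' @param a,b named `GRanges` peak sets.
#' @param minOverlap minimum overlap in bp (>= 1).
#' @return a data.frame with columns `id_a`, `id_b`, one row per pair whose
#'   intersection is at least `minOverlap` bp, sorted by `id_a` then `id_b`.
#' @examples
#' a <- peakSet("chr1", 100, 200, id = "a1")
#' b <- peakSet("chr1", 199, 300, id = "b1")
#' overlapPairs(a, b)
#' @export
overlapPairs <- function(a, b, minOverlap = 1L) {
  .checkPeakSet(a, "a"); .checkPeakSet(b, "b")
  .assertScalarNumber(minOverlap, "minOverlap", min = 1)
  hits <- findOverlaps(a, b, minoverlap = as.integer(minOverlap),
                       ignore.strand = TRUE)
  out <- data.frame(id_a = names(a)[queryHits(hits)],
                    id_b = names(b)[subjectHits(hits)],
                    stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Filter ChIP peaks to the high-confidence, accessible subset
#'
#' Keeps the ChIP peaks that overlap at least one accessible (ATAC) peak by
#' at least `minOverlap` bp — the standard filter that removes peaks falling
#' in closed chromatin.  Input order is preserved.
#'
#' @param chip,atac named `GRanges` peak sets.
#' @param minOverlap minimum overlap in bp.
#' @return the retained subset of `chip`.
#' @export
filterHighConfidence <- function(chip, atac, minOverlap = 1L) {
  .checkPeakSet(chip, "chip"); .checkPeakSet(atac, "atac")
  if (length(atac) == 0L || length(chip) == 0L) return(chip[integer(0)])
  hits <- findOverlaps(chip, atac, minoverlap = as.integer(minOverlap),
                       ignore.strand = TRUE)
  chip[sort(unique(queryHits(hits)))]
}

#' Build a TSS annotation
#'
#' @param geneId unique gene ids.
#' @param chrom chromosome of each TSS.
#' @param pos TSS position, 0-based.
#' @param strand gene strand (`+`/`-`).
#' @return a width-1 `GRanges` named by gene id (the package's genome
#'   annotation object).
#' @export
tssAnnotation <- function(geneId, chrom, pos, strand = "+") {
  if (anyDuplicated(geneId)) stop("gene ids must be unique")
  n <- length(pos)
  gr <- GRanges(as.character(chrom),
                IRanges(as.integer(pos) + 1L, width = rep(1L, n)),
                strand = rep(strand, length.out = n))
  names(gr) <- geneId
  gr
}

# Promoter windows: the half-open window [tss - w, tss + w) around each TSS,
# applied symmetrically regardless of strand.
.promoterWindows <- function(tss, promoterWindow) {
  GRanges(seqnames(tss),
          IRanges(pmax(1L, start(tss) - as.integer(promoterWindow)),
                  start(tss) + as.integer(promoterWindow) - 1L))
}

#' Annotate peaks as promoter or distal
#'
#' A peak is "promoter" iff it overlaps the window of `promoterWindow` bp on
#' either side of any TSS (the window is symmetric, so gene strand is
#' irrelevant to its placement); otherwise it is "distal".
#'
#' @param peaks a named `GRanges` peak set.
#' @param tss a TSS annotation from [tssAnnotation()].
#' @param promoterWindow half-width of the promoter window in bp (> 0).
#' @return a named character vector over the peak ids with values
#'   `"promoter"` or `"distal"`.
#' @export
annotateLocation <- function(peaks, tss, promoterWindow = 1000L) {
  .checkPeakSet(peaks)
  .assertScalarNumber(promoterWindow, "promoterWindow", min = 1)
  out <- setNames(rep("distal", length(peaks)), names(peaks))
  if (length(tss)) {
    win <- .promoterWindows(tss, promoterWindow)
    hits <- findOverlaps(peaks, win, ignore.strand = TRUE)
    out[unique(queryHits(hits))] <- "promoter"
  }
  out
}

#' Merge peak sets into a common universe
#'
#' Takes the union of all intervals, merging overlapping or book-ended
#' (gap 0) intervals, sorts by (chrom, start) and assigns fresh ids
#' `peak_1 ...` in that order.  Idempotent.
#'
#' @param sets a list of named `GRanges` peak sets (or a single one).
#' @return a merged, sorted, renamed `GRanges`.
#' @export
mergeUnion <- function(sets) {
  if (is(sets, "GRanges")) sets <- list(sets)
  if (!length(sets)) stop("at least one peak set is required")
  all <- do.call(c, lapply(sets, function(x) {
    .checkPeakSet(x)
    g <- granges(x)
    strand(g) <- "*"
    names(g) <- NULL
    mcols(g) <- NULL
    g
  }))
  merged <- reduce(sort(all), min.gapwidth = 1L)
  names(merged) <- if (length(merged)) paste0("peak_", seq_along(merged))
                   else character()
  merged
}
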