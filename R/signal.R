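# Comparative occupancy computations on tag-count tables.

#' Depth-normalize a tag-count table
#'
#' Scales every column so that it sums to `normTarget` tags.  Only ratios
#' matter downstream, so the target is an arbitrary fixed constant (default
#' 1e7).
#'
#' @param table a [TagCountTable()].
#' @param normTarget tags per sample after scaling.
#' @return a new, normalized `TagCountTable`; the input is unmodified.
#' @export
normalizeTags <- function(table, normTarget = 1e7) {
  stopifnot(is(table, "TagCountTable"))
  .assertScalarNumber(normTarget, "normTarget", min = 1e-12)
  cnt <- assay(table, "counts")
  cs <- colSums(cnt)
  if (any(cs == 0))
    stop("cannot normalize all-zero sample(s): ",
         paste(colnames(cnt)[cs == 0], collapse = ", "))
  scaled <- sweep(cnt, 2, normTarget / cs, `*`)
  out <- TagCountTable(scaled, colData = colData(table),
                       normalized = TRUE, normTarget = normTarget)
  rowData(out) <- rowData(table)
  out
}

# Average replicate columns of a normalized table for the given sample ids.
.sampleColumn <- function(table, samples, what) {
  cnt <- assay(table, "counts")
  missing <- setdiff(samples, colnames(cnt))
  if (length(missing))
    stop("unknown sample id(s) for '", what, "': ",
         paste(missing, collapse = ", "))
  rowMeans(cnt[, samples, drop = FALSE])
}

#' Pearson correlation between samples
#'
#' Computes the sample-by-sample Pearson correlation of
#' `log2(normalized counts + 1)`, the standard similarity summary for
#' accessibility or occupancy profiles over a common peak universe.
#' Raw tables are normalized first (to 1e7 tags).
#'
#' @param table a [TagCountTable()] with at least two peaks.
#' @return a symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
correlationMatrix <- function(table) {
  stopifnot(is(table, "TagCountTable"))
  if (nrow(table) < 2L) stop("at least two peaks are required")
  if (!isNormalized(table)) table <- normalizeTags(table)
  lg <- log2(assay(table, "counts") + 1)
  sds <- apply(lg, 2, sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(lg)[sds == 0], collapse = ", "))
  r <- cor(lg)
  diag(r) <- 1
  r
}

#' Differentially accessible sites between two samples
#'
#' A peak is "gained" when `(b + pseudocount) / (a + pseudocount)` is at
#' least `foldThreshold` and "lost" in the symmetric case; the threshold is
#' inclusive (a ratio exactly equal to the threshold qualifies).
#'
#' @param a,b aligned named numeric columns over the same peak universe
#'   (same ids in the same order).
#' @param foldThreshold fold-change threshold (> 1).
#' @param pseudocount added to both sides before the ratio.
#' @return `list(gained = ids, lost = ids)`; the two sets are disjoint.
#' @export
differentialSites <- function(a, b, foldThreshold = 2, pseudocount = 1) {
  if (length(a) != length(b) || !identical(names(a), names(b)))
    stop("'a' and 'b' must be aligned to the same peak universe")
  .assertScalarNumber(foldThreshold, "foldThreshold", min = 1 + 1e-12)
  fold <- (b + pseudocount) / (a + pseudocount)
  list(gained = names(a)[fold >= foldThreshold],
       lost = names(a)[1 / fold >= foldThreshold])
}

#' Classify peaks as shared or factor-specific
#'
#' Implements the comparative-occupancy rule: a peak is specific to the
#' factor whose (pseudocounted, replicate-averaged, depth-normalized) tag
#' count exceeds the other's by at least `foldThreshold`; otherwise it is
#' shared.  The threshold is inclusive — a fold change of exactly 2 counts
#' as specific under the default.
#'
#' @param table a normalized [TagCountTable()]; raw input is an error, since
#'   classification must not reflect sequencing depth.
#' @param tf1Samples,tf2Samples sample ids of the two factors' columns;
#'   multiple ids are averaged after normalisation.
#' @param foldThreshold fold-change threshold (> 1), inclusive.
#' @param pseudocount added to both averaged columns.
#' @param peakIds optional subset of peaks to classify (default: all).
#' @return a [S4Vectors::DataFrame] over the classified peaks with columns
#'   `label` (`shared` / `tf1_specific` / `tf2_specific`), `fold` (>= 1,
#'   larger over smaller), `tf1`, `tf2` (the values used);
#'   `metadata(x)$summary` holds the per-label counts.
#' @examples
#' m <- cbind(tf1 = c(8, 4), tf2 = c(4, 8))
#' rownames(m) <- c("p1", "p2")
#' tab <- TagCountTable(m, normalized = TRUE, normTarget = 12)
#' classifySharedSpecific(tab, "tf1", "tf2", pseudocount = 0)
#' @export
classifySharedSpecific <- function(table, tf1Samples, tf2Samples,
                                   foldThreshold = 2, pseudocount = 1,
                                   peakIds = NULL) {
  stopifnot(is(table, "TagCountTable"))
  if (!isNormalized(table))
    stop("classification requires a normalized table (see normalizeTags)")
  .assertScalarNumber(foldThreshold, "foldThreshold", min = 1 + 1e-12)
  .assertScalarNumber(pseudocount, "pseudocount", min = 0)
  x1 <- .sampleColumn(table, tf1Samples, "tf1") + pseudocount
  x2 <- .sampleColumn(table, tf2Samples, "tf2") + pseudocount
  if (pseudocount == 0 && (any(x1 == 0) || any(x2 == 0)))
    stop("pseudocount must be > 0 unless both columns are strictly positive")
  if (!is.null(peakIds)) {
    missing <- setdiff(peakIds, rownames(table))
    if (length(missing))
      stop("peak id(s) outside the universe: ",
           paste(head(missing, 3), collapse = ", "))
    x1 <- x1[peakIds]; x2 <- x2[peakIds]
  }
  fold <- pmax(x1, x2) / pmin(x1, x2)
  label <- rep("shared", length(x1))
  label[fold >= foldThreshold & x1 > x2] <- "tf1_specific"
  label[fold >= foldThreshold & x2 > x1] <- "tf2_specific"
  out <- DataFrame(label = label, fold = fold,
                   tf1 = x1 - pseudocount, tf2 = x2 - pseudocount,
                   row.names = names(x1))
  metadata(out)$summary <- c(
    n_shared = sum(label == "shared"),
    n_tf1_specific = sum(label == "tf1_specific"),
    n_tf2_specific = sum(label == "tf2_specific"))
  metadata(out)$parameters <- list(foldThreshold = foldThreshold,
                                   pseudocount = pseudocount)
  out
}

#' Detect de novo acquired or lost binding at specific sites
#'
#' Given the factor-2 signal at factor-1-specific peaks in wild-type and
#' mutant cells, labels each peak `acquired` when the mutant/WT pseudocount
#' fold is at least `foldThreshold`, `lost` when the WT/mutant fold is, and
#' `unchanged` otherwise (the two conditions are mutually exclusive for any
#' threshold > 1).
#'
#' @param table a normalized [TagCountTable()].
#' @param specificIds peak ids to inspect (typically the factor-1-specific
#'   set from [classifySharedSpecific()]).
#' @param wtSamples,mutSamples sample ids of the factor-2 ChIP in wild-type
#'   and mutant cells; multiple ids are averaged.
#' @param foldThreshold inclusive fold threshold (> 1).
#' @param pseudocount added to both sides.
#' @return a [S4Vectors::DataFrame] over `specificIds` with columns `label`
#'   and `fold` (mutant/WT); `metadata(x)$summary` holds the acquired /
#'   lost / unchanged counts.
#' @export
detectDeNovo <- function(table, specificIds, wtSamples, mutSamples,
                         foldThreshold = 2, pseudocount = 1) {
  stopifnot(is(table, "TagCountTable"))
  if (!isNormalized(table))
    stop("de novo detection requires a normalized table")
  .assertScalarNumber(foldThreshold, "foldThreshold", min = 1 + 1e-12)
  missing <- setdiff(specificIds, rownames(table))
  if (length(missing))
    stop("peak id(s) outside the universe: ",
         paste(head(missing, 3), collapse = ", "))
  wt <- .sampleColumn(table, wtSamples, "wt")[specificIds] + pseudocount
  mut <- .sampleColumn(table, mutSamples, "mutant")[specificIds] + pseudocount
  fold <- mut / wt
  label <- rep("unchanged", length(fold))
  label[fold >= foldThreshold] <- "acquired"
  label[1 / fold >= foldThreshold] <- "lost"
  out <- DataFrame(label = label, fold = fold, row.names = specificIds)
  metadata(out)$summary <- c(n_acquired = sum(label == "acquired"),
                             n_lost = sum(label == "lost"),
                             n_unchanged = sum(label == "unchanged"))
  out
}

#' Order a tag-count table by one sample's signal
#'
#' Reorders the peaks by the chosen column (descending by default, the
#' heat-map convention), breaking ties lexicographically by peak id so the
#' ordering is stable and reproducible.  All other columns are carried
#' along, ready for heat-map export.
#'
#' @param table a [TagCountTable()].
#' @param rankBy sample id to order by.
#' @param descending order direction.
#' @return the reordered `TagCountTable`.
#' @export
rankMatrix <- function(table, rankBy, descending = TRUE) {
  stopifnot(is(table, "TagCountTable"))
  if (!rankBy %in% colnames(table))
    stop("unknown sample id: ", rankBy)
  v <- assay(table, "counts")[, rankBy]
  o <- order(if (descending) -v else v, rownames(table))
  table[o, ]
}
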