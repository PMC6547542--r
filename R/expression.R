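# Bulk expression: differential selection, Z-scores, covariance clustering,
# the 8-way directional grouping, target mapping and Venn overlaps.

# Replicate-mean expression for one (stage, genotype), floored at minExpr.
.stageMean <- function(expr, stage, genotype, minExpr) {
  cd <- colData(expr)
  sel <- cd$stage == stage & cd$genotype == genotype
  if (!any(sel))
    stop("no columns for stage '", stage, "', genotype '", genotype, "'")
  pmax(rowMeans(assay(expr, 1)[, sel, drop = FALSE]), minExpr)
}

.checkExpressionSE <- function(expr) {
  cd <- colData(expr)
  if (is.null(cd$stage) || is.null(cd$genotype))
    stop("expression colData must carry 'stage' and 'genotype'")
  invisible(expr)
}

#' Select differentially affected genes
#'
#' A gene is selected when its replicate-mean expression (floored at
#' `minExpr` to guard folds near zero) differs by at least `foldThreshold`
#' (either direction, inclusive) between the wild type and any other
#' genotype at one or more stages.
#'
#' @param expr a `SummarizedExperiment` with assay on the linear scale and
#'   `colData` columns `stage`, `genotype`, `replicate` (e.g. from
#'   [simulateExpression()]).
#' @param foldThreshold fold-change threshold (> 1), inclusive.
#' @param minExpr expression floor on the linear scale.
#' @param wtGenotype the reference genotype; must be present at every stage.
#' @return selected gene ids (character).
#' @export
selectDifferential <- function(expr, foldThreshold = 2, minExpr = 1,
                               wtGenotype = "WT") {
  .checkExpressionSE(expr)
  .assertScalarNumber(foldThreshold, "foldThreshold", min = 1 + 1e-12)
  cd <- colData(expr)
  stages <- unique(cd$stage)
  mutants <- setdiff(unique(cd$genotype), wtGenotype)
  if (!all(stages %in% cd$stage[cd$genotype == wtGenotype]))
    stop("wild-type columns missing at some stage")
  hit <- rep(FALSE, nrow(expr))
  for (st in stages) {
    wt <- .stageMean(expr, st, wtGenotype, minExpr)
    for (mt in mutants) {
      m <- .stageMean(expr, st, mt, minExpr)
      ratio <- m / wt
      hit <- hit | ratio >= foldThreshold | 1 / ratio >= foldThreshold
    }
  }
  rownames(expr)[hit]
}

#' Row Z-scores
#'
#' Centres every row and scales it to population standard deviation 1
#' (denominator n, the heat-map convention).  Constant rows map to all-zero
#' rows rather than NaN.
#'
#' @param m a numeric matrix with at least 2 columns.
#' @return the Z-score matrix, same dimnames.
#' @export
rowZscore <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("at least 2 columns are required")
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / ifelse(sdp == 0, 1, sdp)
  z[sdp == 0, ] <- 0
  z
}

#' Covariance clustering of expression profiles
#'
#' Agglomerative hierarchical clustering of row Z-score profiles with
#' correlation distance (1 - Pearson r) and average linkage, cut into
#' exactly `K` clusters — the "covariance analysis" stage that groups genes
#' by the shape of their expression pattern across conditions.  Constant
#' (all-zero) profiles are assigned correlation 0 against everything.
#'
#' @param z genes x conditions Z-score matrix (see [rowZscore()]).
#' @param K number of clusters, `1 <= K <= nrow(z)`.
#' @return `list(clusters = <named integer 1..K>, profiles = <K x
#'   conditions matrix of per-cluster mean Z profiles>)`.
#' @export
clusterCovariant <- function(z, K) {
  z <- as.matrix(z)
  if (K < 1L || K > nrow(z))
    stop("K must be between 1 and the number of genes")
  if (K == nrow(z)) {
    cl <- setNames(seq_len(nrow(z)), rownames(z))
  } else if (K == 1L) {
    cl <- setNames(rep(1L, nrow(z)), rownames(z))
  } else {
    r <- suppressWarnings(cor(t(z)))
    r[is.na(r)] <- 0
    diag(r) <- 1
    hc <- hclust(as.dist(1 - r), method = "average")
    cl <- cutree(hc, k = K)
    names(cl) <- rownames(z)
  }
  profiles <- do.call(rbind, lapply(seq_len(K), function(k)
    colMeans(z[cl == k, , drop = FALSE])))
  rownames(profiles) <- paste0("cluster_", seq_len(K))
  list(clusters = cl, profiles = profiles)
}

#' Assign directional expression groups at one cell type
#'
#' Classifies every gene by the direction of its fold change versus wild
#' type in each of the two mutants at the given stage: at least
#' `foldThreshold` up, at least `foldThreshold` down, or unchanged.  Genes
#' changed in at least one mutant fall into one of 8 groups; the fixed group
#' map places the shared responses at the ends (1 both up, 8 both down) and
#' the completely reciprocal responses in the middle (4 mutant-A up /
#' mutant-B down, 5 the reverse):
#'
#' | group | mutant A | mutant B |
#' |-------|----------|----------|
#' | 1 | up | up |
#' | 2 | up | - |
#' | 3 | - | up |
#' | 4 | up | down |
#' | 5 | down | up |
#' | 6 | - | down |
#' | 7 | down | - |
#' | 8 | down | down |
#'
#' @param expr expression `SummarizedExperiment` (linear scale, `colData`
#'   with `stage`/`genotype`).
#' @param cellType the stage to group at.
#' @param foldThreshold inclusive fold threshold (> 1).
#' @param minExpr expression floor.
#' @param wtGenotype reference genotype.
#' @param mutants the two mutant genotypes (axis A first); defaults to the
#'   non-reference genotypes in `colData` order.
#' @return a [S4Vectors::DataFrame] over all genes with columns `group`
#'   (`"1" ... "8"` or `"unchanged"`), `foldA`, `foldB` (mutant/WT),
#'   `dirA`, `dirB` (`up` / `down` / `unchanged`).
#' @export
assignDirectionGroups <- function(expr, cellType, foldThreshold = 2,
                                  minExpr = 1, wtGenotype = "WT",
                                  mutants = NULL) {
  .checkExpressionSE(expr)
  cd <- colData(expr)
  if (!cellType %in% cd$stage)
    stop("unknown cell type: ", cellType)
  if (is.null(mutants))
    mutants <- setdiff(unique(cd$genotype), wtGenotype)
  if (length(mutants) != 2L)
    stop("exactly two mutant genotypes are required")
  wt <- .stageMean(expr, cellType, wtGenotype, minExpr)
  a <- .stageMean(expr, cellType, mutants[1L], minExpr)
  b <- .stageMean(expr, cellType, mutants[2L], minExpr)
  foldA <- a / wt
  foldB <- b / wt
  dirOf <- function(f)
    ifelse(f >= foldThreshold, "up",
           ifelse(1 / f >= foldThreshold, "down", "unchanged"))
  foldA <- unname(foldA); foldB <- unname(foldB)
  dirA <- dirOf(foldA); dirB <- dirOf(foldB)
  key <- paste(dirA, dirB)
  map <- c("up up" = "1", "up unchanged" = "2", "unchanged up" = "3",
           "up down" = "4", "down up" = "5", "unchanged down" = "6",
           "down unchanged" = "7", "down down" = "8",
           "unchanged unchanged" = "unchanged")
  DataFrame(group = unname(map[key]), foldA = foldA, foldB = foldB,
            dirA = dirA, dirB = dirB, row.names = rownames(expr))
}

#' Map peaks to target genes
#'
#' A gene is a target when at least one peak lies within `maxDistance` bp of
#' its TSS (overlap counts as distance zero); one peak may serve several
#' genes.
#'
#' @param peaks a named `GRanges` peak set.
#' @param tss TSS annotation from [tssAnnotation()].
#' @param maxDistance maximum peak-TSS distance in bp.
#' @return a named list, gene id -> character vector of peak ids (genes with
#'   no peak are omitted), in annotation order; peak ids sorted.
#' @export
mapPeaksToGenes <- function(peaks, tss, maxDistance = 1000L) {
  .checkPeakSet(peaks)
  if (!length(tss)) stop("the annotation is empty")
  win <- GRanges(seqnames(tss),
                 IRanges(pmax(1L, start(tss) - as.integer(maxDistance)),
                         start(tss) + as.integer(maxDistance)))
  hits <- findOverlaps(win, peaks, ignore.strand = TRUE)
  m <- data.frame(gene = names(tss)[queryHits(hits)],
                  peak = names(peaks)[subjectHits(hits)])
  m <- m[order(match(m$gene, names(tss)), m$peak), ]
  split(m$peak, factor(m$gene, levels = unique(m$gene)))
}

#' Venn region counts for 2-3 named gene sets
#'
#' Enumerates membership of every element of the union and counts each
#' region of the 2- or 3-set Venn partition; region counts sum to the union
#' size.
#'
#' @param sets a named list of 2 or 3 character vectors.
#' @return a named integer vector; region names join the member set names
#'   with `&` and suffix `_only` for exclusive regions.
#' @export
overlapTargets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
    stop("2 or 3 named sets are supported")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL,
                                                               names(sets)))
  pattern <- apply(member, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  counts <- integer(0)
  for (k in seq_along(sets)) {
    for (combo in utils::combn(names(sets), k, simplify = FALSE)) {
      nm <- paste(combo, collapse = "&")
      label <- if (k == 1L) paste0(nm, "_only") else nm
      counts[label] <- sum(pattern == nm)
    }
  }
  counts
}
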