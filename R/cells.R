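# Single-cell stage: preprocessing, reduction + clustering, markers,
# MST pseudotime and genotype comparison.  All decisions (clustering, tree,
# pseudotime) operate in PCA space; any nonlinear embedding is display-only.

#' Preprocess a single-cell count matrix
#'
#' Removes cells below the count/gene thresholds, scales every remaining
#' cell to the same total (the median of the retained totals), and stores
#' `log2(1 + scaled)` as the `logcounts` assay.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (genes x cells), e.g. from [simulateSingleCells()].
#' @param minCounts minimum total counts per cell.
#' @param minGenes minimum number of detected (> 0) genes per cell.
#' @return the filtered `SingleCellExperiment` with assays `counts` and
#'   `logcounts` and a `totalCounts` column in `colData`.
#' @export
preprocessCells <- function(sce, minCounts = 0, minGenes = 0) {
  stopifnot(is(sce, "SingleCellExperiment"))
  cnt <- assay(sce, "counts")
  totals <- colSums(cnt)
  detected <- colSums(cnt > 0)
  keep <- totals >= minCounts & detected >= minGenes & totals > 0
  if (!any(keep)) stop("all cells removed by filtering")
  sce <- sce[, keep]
  cnt <- assay(sce, "counts")
  totals <- colSums(cnt)
  target <- median(totals)
  scaled <- sweep(cnt, 2, target / totals, `*`)
  SummarizedExperiment::assay(sce, "logcounts") <- log2(1 + scaled)
  colData(sce)$totalCounts <- totals
  sce
}

# Deterministic, permutation-equivariant k-means: farthest-point
# initialization from the grand mean, then Lloyd iterations.
.kmeansDet <- function(x, k) {
  if (k > nrow(x)) stop("k exceeds the number of cells")
  if (k == 1L)
    return(setNames(rep(1L, nrow(x)), rownames(x)))
  centre <- colMeans(x)
  d2 <- rowSums(sweep(x, 2, centre)^2)
  init <- which.max(d2)
  while (length(init) < k) {
    dmin <- apply(vapply(init, function(i)
      rowSums(sweep(x, 2, x[i, ])^2), numeric(nrow(x))), 1, min)
    dmin[init] <- -Inf
    init <- c(init, which.max(dmin))
  }
  fit <- kmeans(x, centers = x[init, , drop = FALSE],
                algorithm = "Lloyd", iter.max = 200L)
  setNames(fit$cluster, rownames(x))
}

#' Reduce dimensionality and cluster cells
#'
#' Principal-component coordinates (top `d`) of the centred `logcounts`,
#' followed by k-means clustering with a deterministic farthest-point
#' initialization (so the result is reproducible and invariant to cell
#' order, up to cluster relabelling).
#'
#' @param sce a preprocessed `SingleCellExperiment` (see
#'   [preprocessCells()]).
#' @param d number of principal components (>= 2).
#' @param k number of clusters.
#' @return `sce` with `reducedDim(sce, "PCA")` set and a `cluster` factor in
#'   `colData`.
#' @export
reduceAndCluster <- function(sce, d = 10L, k = 4L) {
  stopifnot(is(sce, "SingleCellExperiment"))
  if (!"logcounts" %in% names(assays(sce)))
    stop("run preprocessCells() first")
  if (d < 2L) stop("d must be >= 2")
  if (k > ncol(sce)) stop("k exceeds the number of cells")
  m <- t(assay(sce, "logcounts"))
  d <- min(as.integer(d), ncol(m), nrow(m) - 1L)
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = d)
  coords <- pc$x
  rownames(coords) <- colnames(sce)
  reducedDim(sce, "PCA") <- coords
  cl <- .kmeansDet(coords, as.integer(k))
  colData(sce)$cluster <- factor(paste0("k", cl),
                                 levels = paste0("k", seq_len(max(cl))))
  sce
}

#' Rank marker genes per cluster
#'
#' For every cluster with at least 3 cells, ranks genes by the log2 fold
#' change of mean normalized expression in the cluster versus all other
#' cells (pseudocount 1), and reports a two-sided Wilcoxon rank-sum p value
#' on the log expression plus its Benjamini-Hochberg q value across genes.
#' Ties in fold change are broken by p value and then gene id, so the
#' ordering is deterministic.
#'
#' @param sce a clustered `SingleCellExperiment` (see [reduceAndCluster()]),
#'   or any preprocessed one if `clusters` is given.
#' @param clusters optional per-cell cluster labels (defaults to
#'   `colData(sce)$cluster`).
#' @return a named list of data.frames (`gene`, `log2FC`, `p`, `q`), one per
#'   cluster, rows ordered by decreasing log2 fold change; clusters with
#'   fewer than 3 cells are skipped with a warning.
#' @export
findMarkers <- function(sce, clusters = NULL) {
  stopifnot(is(sce, "SingleCellExperiment"))
  if (is.null(clusters)) clusters <- colData(sce)$cluster
  if (is.null(clusters)) stop("no cluster labels available")
  clusters <- as.factor(clusters)
  if (nlevels(droplevels(clusters)) < 2L)
    stop("at least 2 clusters are required")
  lg <- assay(sce, "logcounts")
  lin <- 2^lg - 1
  out <- list()
  for (cl in levels(droplevels(clusters))) {
    inCl <- clusters == cl
    if (sum(inCl) < 3L) {
      warning("cluster '", cl, "' has fewer than 3 cells; skipped")
      next
    }
    fc <- log2((rowMeans(lin[, inCl, drop = FALSE]) + 1) /
               (rowMeans(lin[, !inCl, drop = FALSE]) + 1))
    p <- vapply(seq_len(nrow(lg)), function(i)
      suppressWarnings(wilcox.test(lg[i, inCl], lg[i, !inCl],
                                   exact = FALSE)$p.value), 0)
    p[is.na(p)] <- 1
    df <- data.frame(gene = rownames(lg), log2FC = fc, p = p,
                     q = p.adjust(p, method = "BH"))
    df <- df[order(-df$log2FC, df$p, df$gene), ]
    rownames(df) <- NULL
    out[[cl]] <- df
  }
  out
}

# Geodesic distances between tree nodes (edge weights = Euclidean centroid
# distances), via igraph.
.treeGraph <- function(centroids) {
  k <- nrow(centroids)
  dm <- as.matrix(dist(centroids))
  g <- graph_from_adjacency_matrix(dm, mode = "undirected", weighted = TRUE)
  mst(g)
}

#' Pseudotime ordering along a centroid spanning tree
#'
#' Builds the minimum spanning tree over cluster centroids in reduced space,
#' projects every cell onto its nearest tree edge, and measures pseudotime
#' as distance along the tree from the root centroid to the projection.
#' Branch points are tree nodes of degree >= 3.
#'
#' @param sce a clustered `SingleCellExperiment` with a `PCA` reduced
#'   dimension (see [reduceAndCluster()]), or pass `coords`/`clusters`
#'   directly.
#' @param rootCluster label of the root cluster (e.g. the
#'   earliest-progenitor cluster); must be one of the cluster labels.
#' @param coords,clusters optional explicit coordinates (cells x d) and
#'   per-cell labels, overriding those in `sce`.
#' @return a [`TrajectoryResult-class`].
#' @export
pseudotimeOrder <- function(sce = NULL, rootCluster, coords = NULL,
                            clusters = NULL) {
  if (is.null(coords)) {
    stopifnot(is(sce, "SingleCellExperiment"))
    coords <- reducedDim(sce, "PCA")
    if (is.null(clusters)) clusters <- colData(sce)$cluster
  }
  clusters <- droplevels(as.factor(clusters))
  if (!rootCluster %in% levels(clusters))
    stop("unknown root cluster: ", rootCluster)
  labs <- levels(clusters)
  centroids <- do.call(rbind, lapply(labs, function(l)
    colMeans(coords[clusters == l, , drop = FALSE])))
  rownames(centroids) <- labs

  if (length(labs) == 1L) {
    pt <- sqrt(rowSums(sweep(coords, 2, centroids[1L, ])^2))
    pt <- pt - min(pt)
    return(new("TrajectoryResult", coords = coords, clusters = clusters,
               centroids = centroids,
               treeEdges = matrix(character(), ncol = 2),
               root = rootCluster,
               pseudotime = setNames(pt, rownames(coords)),
               branchPoints = 0L))
  }

  tree <- .treeGraph(centroids)
  edges <- as_edgelist(tree, names = TRUE)
  if (!is.character(edges))
    edges <- matrix(labs[as.integer(edges)], ncol = 2)
  nodeDist <- distances(tree)[match(rootCluster, labs), ]

  # project every cell onto its nearest tree edge, then measure distance
  # from the root along the tree
  nE <- nrow(edges)
  best <- rep(Inf, nrow(coords))
  pt <- numeric(nrow(coords))
  for (e in seq_len(nE)) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    pu <- centroids[u, ]; pv <- centroids[v, ]
    dir <- pv - pu
    len <- sqrt(sum(dir^2))
    rel <- sweep(coords, 2, pu)
    s <- pmin(pmax(as.vector(rel %*% dir) / sum(dir^2), 0), 1)
    proj <- outer(s, dir) + rep(pu, each = nrow(coords))
    d <- sqrt(rowSums((coords - proj)^2))
    iu <- match(u, labs); iv <- match(v, labs)
    along <- pmin(nodeDist[iu] + s * len, nodeDist[iv] + (1 - s) * len)
    upd <- d < best
    best[upd] <- d[upd]
    pt[upd] <- along[upd]
  }
  deg <- degree(tree)
  new("TrajectoryResult", coords = coords, clusters = clusters,
      centroids = centroids, treeEdges = edges, root = rootCluster,
      pseudotime = setNames(pt, rownames(coords)),
      branchPoints = sum(deg >= 3L))
}

# Mean log-expression profile per cluster (genes x clusters).
.clusterProfiles <- function(sce, clusters) {
  lg <- assay(sce, "logcounts")
  vapply(levels(clusters), function(cl)
    rowMeans(lg[, clusters == cl, drop = FALSE]), numeric(nrow(lg)))
}

#' Compare two genotypes' trajectories and cluster composition
#'
#' Matches clusters across genotypes by Pearson correlation of their mean
#' log-expression profiles (greedy one-to-one matching over pairs with
#' correlation at least `corCutoff`), reports clusters present in one
#' genotype only, the branch-point counts, and — within every matched
#' cluster pair — per-gene differential expression between genotypes
#' (log2 fold change with pseudocount 1, two-sided Wilcoxon rank-sum p,
#' Benjamini-Hochberg q).
#'
#' @param resA,resB [`TrajectoryResult-class`] objects for the two
#'   genotypes.
#' @param sceA,sceB the matching preprocessed `SingleCellExperiment`s (same
#'   gene universe).
#' @param corCutoff minimum profile correlation for two clusters to match.
#' @return a list: `clusterCountDiff` (B minus A), `specificA`/`specificB`
#'   (unmatched cluster labels), `matches` (data.frame clusterA, clusterB,
#'   correlation), `branchPointsA`/`branchPointsB`, and `differential` (a
#'   named list of per-matched-pair data.frames `gene`, `log2FC`, `p`, `q`,
#'   fold oriented B over A).
#' @export
compareGenotypes <- function(resA, sceA, resB, sceB, corCutoff = 0.9) {
  stopifnot(is(resA, "TrajectoryResult"), is(resB, "TrajectoryResult"))
  if (!identical(rownames(sceA), rownames(sceB)))
    stop("the two matrices must share one gene universe")
  clA <- droplevels(resA@clusters)
  clB <- droplevels(resB@clusters)
  profA <- .clusterProfiles(sceA, clA)
  profB <- .clusterProfiles(sceB, clB)
  r <- suppressWarnings(cor(profA, profB))
  r[is.na(r)] <- 0

  pairs <- which(r >= corCutoff, arr.ind = TRUE)
  matches <- data.frame(clusterA = character(), clusterB = character(),
                        correlation = numeric())
  if (nrow(pairs)) {
    ord <- order(-r[pairs])
    usedA <- character(); usedB <- character()
    for (i in ord) {
      a <- colnames(profA)[pairs[i, 1L]]
      b <- colnames(profB)[pairs[i, 2L]]
      if (a %in% usedA || b %in% usedB) next
      usedA <- c(usedA, a); usedB <- c(usedB, b)
      matches <- rbind(matches, data.frame(
        clusterA = a, clusterB = b,
        correlation = r[pairs[i, 1L], pairs[i, 2L]]))
    }
  }
  specificA <- setdiff(levels(clA), matches$clusterA)
  specificB <- setdiff(levels(clB), matches$clusterB)

  lgA <- assay(sceA, "logcounts"); lgB <- assay(sceB, "logcounts")
  linA <- 2^lgA - 1; linB <- 2^lgB - 1
  differential <- list()
  for (i in seq_len(nrow(matches))) {
    inA <- clA == matches$clusterA[i]
    inB <- clB == matches$clusterB[i]
    fc <- log2((rowMeans(linB[, inB, drop = FALSE]) + 1) /
               (rowMeans(linA[, inA, drop = FALSE]) + 1))
    p <- vapply(seq_len(nrow(lgA)), function(g)
      suppressWarnings(wilcox.test(lgB[g, inB], lgA[g, inA],
                                   exact = FALSE)$p.value), 0)
    p[is.na(p)] <- 1
    df <- data.frame(gene = rownames(lgA), log2FC = fc, p = p,
                     q = p.adjust(p, method = "BH"))
    df <- df[order(df$p, -abs(df$log2FC), df$gene), ]
    rownames(df) <- NULL
    differential[[paste(matches$clusterA[i], matches$clusterB[i],
                        sep = "~")]] <- df
  }
  list(clusterCountDiff = nlevels(clB) - nlevels(clA),
       specificA = specificA, specificB = specificB,
       matches = matches,
       branchPointsA = resA@branchPoints,
       branchPointsB = resB@branchPoints,
       differential = differential)
}
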