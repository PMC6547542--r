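test_that("preprocessing filters, equalizes depth and log-transforms", {
  m <- matrix(c(10, 0, 5, 0, 0, 0, 40, 2, 8), 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  sce <- SingleCellExperiment(assays = list(counts = m))
  # a zero-count cell is removed at any positive threshold (and even at 0,
  # since normalisation needs a positive total)
  out <- preprocessCells(sce, minCounts = 0)
  expect_identical(colnames(out), c("c1", "c3"))
  tot <- colSums(2^assay(out, "logcounts") - 1)
  expect_equal(unname(tot), rep(median(c(15, 50)), 2))
  out2 <- preprocessCells(sce, minCounts = 20)
  expect_identical(colnames(out2), "c3")
  expect_error(preprocessCells(sce, minCounts = 1000), "all cells")
})

test_that("clustering recovers planted clusters and is order-invariant", {
  skip_if_not_installed("mclust")
  cfg <- smallConfig(41)
  sce <- preprocessCells(simulateSingleCells(cfg)$WT)
  k <- length(unique(colData(sce)$trueCluster))
  cl <- reduceAndCluster(sce, 10, k)
  ari <- mclust::adjustedRandIndex(colData(cl)$cluster,
                                   colData(cl)$trueCluster)
  expect_gte(ari, 0.9)
  # k = 1 puts everything together
  one <- reduceAndCluster(sce, 5, 1)
  expect_length(unique(colData(one)$cluster), 1)
  # identical rerun; permuted cell order gives the same partition
  cl2 <- reduceAndCluster(sce, 10, k)
  expect_identical(colData(cl)$cluster, colData(cl2)$cluster)
  set.seed(42)
  perm <- sample(ncol(sce))
  clp <- reduceAndCluster(sce[, perm], 10, k)
  a <- colData(cl)$cluster[match(colnames(sce), colnames(cl))]
  b <- colData(clp)$cluster[match(colnames(sce), colnames(clp))]
  expect_equal(mclust::adjustedRandIndex(a, b), 1)
  expect_error(reduceAndCluster(sce, 10, ncol(sce) + 1), "exceeds")
})

test_that("marker ranking surfaces exclusive and planted markers", {
  # a gene expressed only in cluster A tops A's marker list
  m <- matrix(1, 4, 30, dimnames = list(paste0("g", 1:4),
                                        paste0("c", 1:30)))
  labs <- rep(c("A", "B"), each = 15)
  m[1, labs == "A"] <- 200
  sce <- preprocessCells(SingleCellExperiment(
    assays = list(counts = m)))
  mk <- findMarkers(sce, labs)
  expect_equal(mk$A$gene[1], "g1")
  # identical expression: fold changes all zero
  flat <- preprocessCells(SingleCellExperiment(
    assays = list(counts = matrix(7, 4, 30,
                                  dimnames = dimnames(m)))))
  mkFlat <- findMarkers(flat, labs)
  expect_true(all(abs(mkFlat$A$log2FC) < 1e-12))
  # planted markers recovered among the top 20 per cluster
  cfg <- smallConfig(43)
  sce2 <- preprocessCells(simulateSingleCells(cfg)$mutA)
  mk2 <- findMarkers(sce2, colData(sce2)$trueCluster)
  for (cl in names(mk2)) {
    planted <- rownames(sce2)[rowData(sce2)$role == paste0("marker_", cl)]
    expect_gte(sum(head(mk2[[cl]]$gene, 20) %in% planted), 9)
  }
  expect_warning(findMarkers(sce, c(rep("A", 2), rep("B", 28))),
                 "fewer than 3")
})

test_that("pseudotime follows latent time on a noiseless linear lineage", {
  cfg <- smallConfig(44, trajectoryTopology = "linear", scNoiseSd = 0,
                     scPoisson = FALSE, extraClusterInMutant = FALSE)
  sce <- preprocessCells(simulateSingleCells(cfg)$WT)
  k <- length(unique(colData(sce)$trueCluster))
  sce <- reduceAndCluster(sce, 10, k)
  mt <- tapply(colData(sce)$latentTime, colData(sce)$cluster, mean)
  tr <- pseudotimeOrder(sce, names(which.min(mt)))
  rho <- cor(pseudotime(tr), colData(sce)$latentTime,
             method = "spearman")
  expect_gte(rho, 0.99)
  expect_equal(branchPoints(tr), 0L)
  expect_true(all(pseudotime(tr) >= 0))
  # spanning tree over k clusters has k - 1 edges
  expect_equal(nrow(tr@treeEdges), k - 1L)
  # root-cluster cells sit at the early end
  expect_lt(mean(pseudotime(tr)[cellClusters(tr) == tr@root]),
            mean(pseudotime(tr)))
  expect_error(pseudotimeOrder(sce, "nope"), "unknown root")
})

test_that("a clean bifurcation yields exactly one branch point", {
  cfg <- smallConfig(45, trajectoryTopology = "bifurcating",
                     scNoiseSd = 0, scPoisson = FALSE,
                     extraClusterInMutant = FALSE)
  sce <- preprocessCells(simulateSingleCells(cfg)$WT)
  k <- length(unique(colData(sce)$trueCluster))
  sce <- reduceAndCluster(sce, 10, k)
  mt <- tapply(colData(sce)$latentTime, colData(sce)$cluster, mean)
  tr <- pseudotimeOrder(sce, names(which.min(mt)))
  expect_equal(branchPoints(tr), 1L)
})

test_that("a single cluster degenerates gracefully", {
  set.seed(46)
  coords <- matrix(rnorm(60), 30, 2,
                   dimnames = list(paste0("c", 1:30), NULL))
  tr <- pseudotimeOrder(rootCluster = "k1", coords = coords,
                        clusters = rep("k1", 30))
  expect_equal(branchPoints(tr), 0L)
  expect_true(all(is.finite(pseudotime(tr))))
  expect_true(all(pseudotime(tr) >= 0))
})

test_that("genotype comparison flags the mutant-only cluster", {
  cfg <- smallConfig(47)   # bifurcating, extra cluster in the mutant
  cells <- simulateSingleCells(cfg)
  res <- list(); sces <- list()
  for (gt in names(cells)) {
    sce <- preprocessCells(cells[[gt]])
    k <- length(unique(colData(sce)$trueCluster))
    sce <- reduceAndCluster(sce, 10, k)
    mt <- tapply(colData(sce)$latentTime, colData(sce)$cluster, mean)
    res[[gt]] <- pseudotimeOrder(sce, names(which.min(mt)))
    sces[[gt]] <- sce
  }
  cmp <- compareGenotypes(res$WT, sces$WT, res$mutA, sces$mutA)
  expect_equal(cmp$clusterCountDiff, 1L)
  expect_length(cmp$specificB, 1)
  expect_length(cmp$specificA, 0)
  # self-comparison is the identity
  self <- compareGenotypes(res$WT, sces$WT, res$WT, sces$WT)
  expect_equal(self$clusterCountDiff, 0L)
  expect_length(self$specificA, 0)
  expect_length(self$specificB, 0)
  expect_equal(self$branchPointsA, self$branchPointsB)
  expect_error(compareGenotypes(res$WT, sces$WT[1:50, ], res$mutA,
                                sces$mutA), "gene universe")
})

test_that("a genotype-wide expression loss shows up in every matched pair", {
  cfg <- smallConfig(48, extraClusterInMutant = FALSE)
  cells <- simulateSingleCells(cfg)
  # knock one flat gene down fourfold across all mutant cells
  flatGene <- rownames(cells$WT)[match("flat",
                                       rowData(cells$WT)$role)]
  mutCounts <- assay(cells$mutA, "counts")
  mutCounts[flatGene, ] <- round(mutCounts[flatGene, ] / 4)
  cellsMut <- SingleCellExperiment(
    assays = list(counts = mutCounts),
    colData = colData(cells$mutA), rowData = rowData(cells$mutA))
  res <- list(); sces <- list()
  input <- list(WT = cells$WT, mutA = cellsMut)
  for (gt in names(input)) {
    sce <- preprocessCells(input[[gt]])
    k <- length(unique(colData(sce)$trueCluster))
    sce <- reduceAndCluster(sce, 10, k)
    mt <- tapply(colData(sce)$latentTime, colData(sce)$cluster, mean)
    res[[gt]] <- pseudotimeOrder(sce, names(which.min(mt)))
    sces[[gt]] <- sce
  }
  cmp <- compareGenotypes(res$WT, sces$WT, res$mutA, sces$mutA)
  expect_gt(nrow(cmp$matches), 0)
  for (df in cmp$differential) {
    row <- df[df$gene == flatGene, ]
    expect_lt(row$log2FC, -1)
    expect_lt(row$q, 0.05)
  }
})
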