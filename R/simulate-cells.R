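# Single-cell simulator: cells are drawn along a cluster chain laid out on
# the chosen lineage topology.  Expression (log2 scale) is the sum of a
# baseline, a latent-time gradient carried by a dedicated gene block,
# branch-specific ramps that switch on past the branch point, and exclusive
# per-cluster marker bumps; the optional mutant-only "extra" cluster is an
# off-trajectory program (markers only), emulating an additional lineage
# that the wild type does not produce.

# Cluster layout per topology: depth is the position along the chain
# (latent time t in ((depth-1) + [0.1, 0.9]) / maxDepth, so consecutive
# clusters are separated by gaps in t).
.scLayout <- function(topology) {
  switch(topology,
    linear = data.frame(
      cluster = paste0("C", 1:4),
      branch = "trunk", depth = 1:4),
    bifurcating = data.frame(
      cluster = paste0("C", 1:6),
      branch = c("trunk", "trunk", "armA", "armA", "armB", "armB"),
      depth = c(1, 2, 3, 4, 3, 4)),
    multifurcating = data.frame(
      cluster = paste0("C", 1:8),
      branch = c("trunk", "trunk", rep(c("armA", "armB", "armC"),
                                       each = 2)),
      depth = c(1, 2, rep(c(3, 4), 3))),
    stop("unknown trajectory topology: ", topology))
}

#' Simulate single-cell count matrices with a planted lineage
#'
#' Draws `nCellsPerGenotype` cells for the first two genotypes along the
#' configured `trajectoryTopology`.  When `extraClusterInMutant` is set, an
#' `extraClusterFraction` of the second genotype's cells form one additional
#' planted cluster with its own marker program, absent from the first
#' genotype.  Counts are Poisson around the planted means (with gaussian
#' log-scale jitter of SD `scNoiseSd`) when `scPoisson` is `TRUE`, or the
#' planted means themselves when it is `FALSE` (the noise-free mode used for
#' oracle checks).
#'
#' @param config a [SimulationConfig()] with `nCellsPerGenotype >= 20`.
#' @return a named list of [SingleCellExperiment::SingleCellExperiment],
#'   one per genotype, each with a `counts` assay (genes x cells) and truth
#'   in `colData`: `genotype`, `latentTime`, `branch`, `trueCluster`;
#'   `rowData$role` records each gene's planted role.
#' @export
simulateSingleCells <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@nCellsPerGenotype < 20L)
    stop("at least 20 cells per genotype are required")
  layout <- .scLayout(config@trajectoryTopology)
  maxDepth <- max(layout$depth)
  tBranch <- max(layout$depth[layout$branch == "trunk"]) / maxDepth
  arms <- setdiff(unique(layout$branch), "trunk")

  nMark <- config@scMarkersPerCluster
  nGrad <- config@scGradientGenes
  nRamp <- 15L
  allClusters <- c(layout$cluster,
                   if (config@extraClusterInMutant) "extra")
  need <- nGrad + nRamp * length(arms) + nMark * length(allClusters)
  if (need > config@nScGenes)
    stop("nScGenes too small: ", need, " structural genes required")

  geneIds <- sprintf("scgene_%03d", seq_len(config@nScGenes))
  gradIdx <- seq_len(nGrad)
  rampIdx <- lapply(seq_along(arms), function(i)
    nGrad + (i - 1L) * nRamp + seq_len(nRamp))
  names(rampIdx) <- arms
  markStart <- nGrad + nRamp * length(arms)
  markIdx <- lapply(seq_along(allClusters), function(i)
    markStart + (i - 1L) * nMark + seq_len(nMark))
  names(markIdx) <- allClusters
  role <- rep("flat", config@nScGenes)
  role[gradIdx] <- "gradient"
  for (a in arms) role[rampIdx[[a]]] <- paste0("ramp_", a)
  for (cl in allClusters) role[markIdx[[cl]]] <- paste0("marker_", cl)

  genotypes <- config@genotypes[1:2]
  .withSeed(.childSeed(config@seed, "cells"), {
    slopes <- runif(nGrad, 2, 4) * rep_len(c(1, -1), nGrad)
    out <- list()
    for (g in seq_along(genotypes)) {
      gt <- genotypes[g]
      n <- config@nCellsPerGenotype
      hasExtra <- config@extraClusterInMutant && g == 2L
      nExtra <- if (hasExtra) round(config@extraClusterFraction * n) else 0L
      nTraj <- n - nExtra
      ci <- sample(nrow(layout), nTraj, replace = TRUE)
      cluster <- c(layout$cluster[ci], rep("extra", nExtra))
      branch <- c(layout$branch[ci], rep("extra", nExtra))
      depth <- layout$depth[ci]
      t <- c((depth - 1 + 0.1 + 0.8 * runif(nTraj)) / maxDepth,
             runif(nExtra))
      onTraj <- c(rep(TRUE, nTraj), rep(FALSE, nExtra))

      eta <- matrix(config@scBaseline, nrow = n, ncol = config@nScGenes)
      eta[onTraj, gradIdx] <- config@scBaseline +
        outer(t[onTraj], slopes)
      for (a in arms) {
        onArm <- which(branch == a)
        if (length(onArm))
          eta[onArm, rampIdx[[a]]] <- config@scBaseline +
            4 * (t[onArm] - tBranch) / (1 - tBranch)
      }
      for (cl in allClusters) {
        inCl <- which(cluster == cl)
        if (length(inCl))
          eta[inCl, markIdx[[cl]]] <- eta[inCl, markIdx[[cl]]] +
            config@scMarkerStrength
      }
      if (config@scNoiseSd > 0)
        eta <- eta + rnorm(length(eta), 0, config@scNoiseSd)
      counts <- if (config@scPoisson)
        matrix(rpois(length(eta), 2^eta), nrow = n) else 2^eta
      cellIds <- sprintf("%s_cell_%04d", gt, seq_len(n))
      dimnames(counts) <- list(cellIds, geneIds)
      sce <- SingleCellExperiment(
        assays = list(counts = t(counts)),
        colData = DataFrame(genotype = gt, latentTime = t,
                            branch = branch, trueCluster = cluster,
                            row.names = cellIds),
        rowData = DataFrame(role = role, row.names = geneIds))
      out[[gt]] <- sce
    }
    out
  })
}
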