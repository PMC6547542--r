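#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  The generator emulates, at
#' desk scale, a two-factor ChIP-seq compendium over a shared peak universe
#' (two factors by three genotypes), matched chromatin accessibility, a
#' five-stage by three-genotype bulk expression series and two genotypes of
#' single-cell count matrices carrying a branched lineage, with every planted
#' structure recorded as ground truth.
#'
#' @slot seed master seed; each generator derives its own stream from it.
#' @slot nChroms,chromLength genome shape: number of chromosomes and length
#'   of each in bp.
#' @slot nGenes number of genes (TSS records) to place.
#' @slot peakWidth width of every simulated peak in bp.
#' @slot nPeaksShared,nPeaksTf1Specific,nPeaksTf2Specific,nBackground peak
#'   class counts making up the landscape.
#' @slot promoterFraction fraction of each peak class placed inside promoter
#'   windows (the remainder is distal).
#' @slot effectFold expected tag-count ratio at factor-specific peaks
#'   (>= 1).
#' @slot compensatedFraction fraction of factor-1-specific peaks that gain
#'   factor-2 signal in mutant genotypes (de novo acquisition), in [0, 1].
#' @slot dispersion negative-binomial dispersion of tag counts
#'   (var = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @slot meanDepth expected tags at an occupied peak.
#' @slot backgroundDepth expected tags at an unoccupied peak.
#' @slot nReplicates ChIP/ATAC replicates per (factor, genotype).
#' @slot backgroundAccessibleFraction fraction of background peaks marked
#'   accessible (so they survive the ATAC filter).
#' @slot nullGenotypes genotypes in which factor 1 cannot bind DNA; its
#'   counts there are drawn from the background distribution.
#' @slot stages,genotypes ordered stage and genotype labels; the first
#'   genotype is the wild type.
#' @slot groupProportions length-9 simplex: probabilities of directional
#'   expression groups 1..8 followed by "unchanged".
#' @slot expressionFold planted fold change of grouped genes vs wild type.
#' @slot expressionNoiseSd replicate noise SD on the log2 expression scale.
#' @slot exprReplicates bulk expression replicates per (stage, genotype).
#' @slot promoterWindow bp on each side of a TSS that count as promoter.
#' @slot motifRatePromoter,motifRateDistal Poisson means of the number of
#'   planted motif instances in promoter and distal peaks.
#' @slot nCellsPerGenotype single cells per genotype (>= 20).
#' @slot nScGenes genes in the single-cell matrices.
#' @slot trajectoryTopology `"linear"`, `"bifurcating"` or
#'   `"multifurcating"`.
#' @slot extraClusterInMutant if `TRUE` the second genotype carries one
#'   additional planted cluster absent from the first.
#' @slot extraClusterFraction fraction of mutant cells in the extra cluster.
#' @slot scMarkersPerCluster planted marker genes per single-cell cluster.
#' @slot scMarkerStrength marker elevation on the log2 scale.
#' @slot scGradientGenes genes carrying the latent-time gradient.
#' @slot scBaseline baseline log2 expression of single-cell genes.
#' @slot scNoiseSd gaussian noise SD on the log2 single-cell scale.
#' @slot scPoisson if `TRUE`, Poisson-sample integer counts around the
#'   planted means; if `FALSE`, return the means themselves (noise-free).
#'
#' @seealso [SimulationConfig()] for the user constructor.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nChroms = "integer", chromLength = "numeric",
    nGenes = "integer", peakWidth = "integer",
    nPeaksShared = "integer", nPeaksTf1Specific = "integer",
    nPeaksTf2Specific = "integer", nBackground = "integer",
    promoterFraction = "numeric",
    effectFold = "numeric", compensatedFraction = "numeric",
    dispersion = "numeric", meanDepth = "numeric",
    backgroundDepth = "numeric", nReplicates = "integer",
    backgroundAccessibleFraction = "numeric",
    nullGenotypes = "character",
    stages = "character", genotypes = "character",
    groupProportions = "numeric",
    expressionFold = "numeric", expressionNoiseSd = "numeric",
    exprReplicates = "integer",
    promoterWindow = "integer",
    motifRatePromoter = "numeric", motifRateDistal = "numeric",
    nCellsPerGenotype = "integer", nScGenes = "integer",
    trajectoryTopology = "character",
    extraClusterInMutant = "logical", extraClusterFraction = "numeric",
    scMarkersPerCluster = "integer", scMarkerStrength = "numeric",
    scGradientGenes = "integer", scBaseline = "numeric",
    scNoiseSd = "numeric", scPoisson = "logical"
  ),
  prototype(
    seed = 1L,
    nChroms = 4L, chromLength = 2e6,
    nGenes = 1200L, peakWidth = 200L,
    nPeaksShared = 1000L, nPeaksTf1Specific = 400L,
    nPeaksTf2Specific = 400L, nBackground = 200L,
    promoterFraction = 0.5,
    effectFold = 4, compensatedFraction = 0.3,
    dispersion = 0.1, meanDepth = 100,
    backgroundDepth = 5, nReplicates = 3L,
    backgroundAccessibleFraction = 0.5,
    nullGenotypes = c("mutA", "mutB"),
    stages = c("ESC", "Flk1", "HE1", "HE2", "Prog"),
    genotypes = c("WT", "mutA", "mutB"),
    groupProportions = c(rep(0.05, 8), 0.6),
    expressionFold = 4, expressionNoiseSd = 0.1,
    exprReplicates = 3L,
    promoterWindow = 1000L,
    motifRatePromoter = 4, motifRateDistal = 0.7,
    nCellsPerGenotype = 300L, nScGenes = 200L,
    trajectoryTopology = "bifurcating",
    extraClusterInMutant = TRUE, extraClusterFraction = 0.15,
    scMarkersPerCluster = 10L, scMarkerStrength = 3,
    scGradientGenes = 50L, scBaseline = 5,
    scNoiseSd = 0.3, scPoisson = TRUE
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (abs(sum(object@groupProportions) - 1) > 1e-9 ||
      length(object@groupProportions) != 9L ||
      any(object@groupProportions < 0))
    msg <- c(msg, "groupProportions must be 9 non-negative values summing to 1")
  if (object@effectFold < 1) msg <- c(msg, "effectFold must be >= 1")
  if (object@compensatedFraction < 0 || object@compensatedFraction > 1)
    msg <- c(msg, "compensatedFraction must be in [0, 1]")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@promoterFraction < 0 || object@promoterFraction > 1)
    msg <- c(msg, "promoterFraction must be in [0, 1]")
  if (length(object@genotypes) < 2L)
    msg <- c(msg, "at least two genotypes (WT plus one mutant) are required")
  if (anyDuplicated(object@genotypes) || anyDuplicated(object@stages))
    msg <- c(msg, "stage and genotype labels must be unique")
  if (!object@trajectoryTopology %in%
        c("linear", "bifurcating", "multifurcating"))
    msg <- c(msg, "trajectoryTopology must be linear, bifurcating or multifurcating")
  if (!all(object@nullGenotypes %in% object@genotypes))
    msg <- c(msg, "nullGenotypes must be a subset of genotypes")
  if (object@genotypes[1L] %in% object@nullGenotypes)
    msg <- c(msg, "the first genotype (wild type) cannot be binding-null")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' All arguments default to the package's reference desk-scale conditions:
#' a 2,000-peak landscape (1,000 shared, 400 specific to each factor, 200
#' background) over an 8 Mb genome with 1,200 genes,
#' a fourfold planted occupancy effect at negative-binomial dispersion 0.1,
#' a five-stage/three-genotype expression series, and 300 cells per genotype
#' on a bifurcating lineage with one mutant-only extra cluster.
#'
#' @param seed master seed (integer).
#' @param ... any slot of [`SimulationConfig-class`] by name.
#' @return a validated [`SimulationConfig-class`] object.
#' @examples
#' cfg <- SimulationConfig(seed = 7, nGenes = 50L, nPeaksShared = 20L)
#' cfg
#' @export
SimulationConfig <- function(seed = 1L, ...) {
  args <- list(...)
  slots <- slotNames("SimulationConfig")
  bad <- setdiff(names(args), slots)
  if (length(bad))
    stop("unknown SimulationConfig fields: ", paste(bad, collapse = ", "))
  intSlots <- slots[vapply(slots, function(s)
    is(getSlots("SimulationConfig")[[s]], "integer") ||
      getSlots("SimulationConfig")[[s]] == "integer", logical(1))]
  for (s in intersect(names(args), intSlots)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("SimulationConfig", seed = as.integer(seed)), args))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genome: ", object@nChroms, " x ",
      format(object@chromLength, big.mark = ","), " bp, ",
      object@nGenes, " genes\n", sep = "")
  cat("  peaks: ", object@nPeaksShared, " shared / ",
      object@nPeaksTf1Specific, " tf1 / ", object@nPeaksTf2Specific,
      " tf2 / ", object@nBackground, " background; effect fold ",
      object@effectFold, ", dispersion ", object@dispersion, "\n", sep = "")
  cat("  expression: ", length(object@stages), " stages x ",
      length(object@genotypes), " genotypes x ", object@exprReplicates,
      " reps\n", sep = "")
  cat("  cells: ", object@nCellsPerGenotype, " per genotype, ",
      object@trajectoryTopology, " topology",
      if (object@extraClusterInMutant) ", extra mutant cluster", "\n",
      sep = "")
})

#' Tag-count table over a peak universe
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `counts`
#' assay holds non-negative per-peak signal (rows are peaks, columns are
#' samples), plus the normalisation state.  When `normalized` is `TRUE`
#' every column sums to `normTarget`.
#'
#' @slot normalized whether columns have been depth-normalized.
#' @slot normTarget the per-column tag total after normalisation.
#' @seealso [TagCountTable()], [normalizeTags()]
#' @export
setClass("TagCountTable",
  contains = "SummarizedExperiment",
  representation(normalized = "logical", normTarget = "numeric"),
  prototype(normalized = FALSE, normTarget = NA_real_)
)

setValidity("TagCountTable", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    return("a 'counts' assay is required")
  cnt <- assay(object, "counts")
  if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique peak ids (rownames) are required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "unique sample ids (colnames) are required")
  if (object@normalized && ncol(cnt) > 0) {
    cs <- colSums(cnt)
    if (any(abs(cs - object@normTarget) > 1e-6 * object@normTarget))
      msg <- c(msg, "normalized table columns must sum to normTarget")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a tag-count table
#'
#' @param counts peaks x samples matrix of non-negative signal with peak ids
#'   as rownames and sample ids as colnames.
#' @param colData optional per-sample annotation (`DataFrame` or
#'   data.frame), e.g. factor and genotype.
#' @param normalized,normTarget normalisation state; raw tables use the
#'   defaults.
#' @return a [`TagCountTable-class`] object.
#' @examples
#' m <- matrix(rpois(12, 10), 4, 3,
#'             dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
#' TagCountTable(m)
#' @export
TagCountTable <- function(counts, colData = NULL, normalized = FALSE,
                          normTarget = NA_real_) {
  counts <- as.matrix(counts)
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = colData)
  new("TagCountTable", se, normalized = normalized, normTarget = normTarget)
}

#' @describeIn TagCountTable whether the table has been depth-normalized.
#' @param x a `TagCountTable`.
#' @export
isNormalized <- function(x) {
  stopifnot(is(x, "TagCountTable"))
  x@normalized
}

#' @describeIn TagCountTable the per-column total used for normalisation
#'   (`NA` for raw tables).
#' @export
normTarget <- function(x) {
  stopifnot(is(x, "TagCountTable"))
  x@normTarget
}

setMethod("show", "TagCountTable", function(object) {
  cat("TagCountTable: ", nrow(object), " peaks x ", ncol(object),
      " samples (", if (object@normalized)
        paste0("normalized to ", format(object@normTarget)) else "raw",
      ")\n", sep = "")
  callNextMethod()
})

#' Position weight matrix
#'
#' A base-probability matrix describing a binding motif (for instance an
#' Sp-family GC box), together with the background base composition and a
#' log-odds score threshold used by the scanner.
#'
#' @slot name motif name.
#' @slot probs L x 4 matrix of per-position base probabilities, columns
#'   A, C, G, T; every row sums to 1.
#' @slot background length-4 background base distribution (sums to 1).
#' @slot scoreThreshold log2-odds score (bits) above which a window is a
#'   hit; `NA` means "use 80% of the maximum achievable score".
#' @seealso [PositionWeightMatrix()], [scanPWM()]
#' @export
setClass("PositionWeightMatrix",
  representation(name = "character", probs = "matrix",
                 background = "numeric", scoreThreshold = "numeric"),
  prototype(background = rep(0.25, 4), scoreThreshold = NA_real_)
)

setValidity("PositionWeightMatrix", function(object) {
  msg <- character()
  p <- object@probs
  if (ncol(p) != 4L) msg <- c(msg, "probs must have 4 columns (A, C, G, T)")
  if (nrow(p) < 4L) msg <- c(msg, "motif length must be >= 4")
  if (ncol(p) == 4L && any(abs(rowSums(p) - 1) > 1e-9))
    msg <- c(msg, "every probs row must sum to 1")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9 ||
      any(object@background <= 0))
    msg <- c(msg, "background must be 4 positive values summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a position weight matrix
#'
#' @param name motif name.
#' @param probs L x 4 base-probability matrix (columns A, C, G, T).
#' @param background background base distribution; uniform by default.
#' @param scoreThreshold log2-odds hit threshold in bits; `NA` (default)
#'   uses 80% of the maximum achievable score at scan time.
#' @return a [`PositionWeightMatrix-class`] object.
#' @examples
#' pwm <- spLikePWM()
#' pwmConsensus(pwm)
#' @export
PositionWeightMatrix <- function(name, probs, background = rep(0.25, 4),
                                 scoreThreshold = NA_real_) {
  probs <- as.matrix(probs)
  colnames(probs) <- c("A", "C", "G", "T")
  new("PositionWeightMatrix", name = name, probs = probs,
      background = background, scoreThreshold = scoreThreshold)
}

setMethod("show", "PositionWeightMatrix", function(object) {
  cat("PositionWeightMatrix '", object@name, "': length ",
      nrow(object@probs), ", consensus ", pwmConsensus(object), "\n",
      sep = "")
})

#' Trajectory inference result
#'
#' Reduced coordinates, cluster labels, the minimum spanning tree over
#' cluster centroids, per-cell pseudotime measured along the tree from the
#' root centroid, and the number of branch points (tree nodes of degree
#' >= 3).
#'
#' @slot coords cells x d reduced coordinates.
#' @slot clusters per-cell cluster label (factor, named by cell id).
#' @slot centroids cluster x d centroid coordinates.
#' @slot treeEdges 2-column character matrix of centroid tree edges.
#' @slot root root cluster label.
#' @slot pseudotime per-cell pseudotime (named numeric, >= 0).
#' @slot branchPoints number of tree nodes with degree >= 3.
#' @seealso [pseudotimeOrder()]
#' @export
setClass("TrajectoryResult",
  representation(coords = "matrix", clusters = "factor",
                 centroids = "matrix", treeEdges = "matrix",
                 root = "character", pseudotime = "numeric",
                 branchPoints = "integer")
)

setValidity("TrajectoryResult", function(object) {
  msg <- character()
  k <- nrow(object@centroids)
  if (k > 1 && nrow(object@treeEdges) != k - 1L)
    msg <- c(msg, "centroid tree must have exactly k - 1 edges")
  if (any(object@pseudotime < 0)) msg <- c(msg, "pseudotime must be >= 0")
  if (!object@root %in% levels(object@clusters))
    msg <- c(msg, "root must be one of the cluster labels")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrajectoryResult", function(object) {
  cat("TrajectoryResult: ", length(object@pseudotime), " cells, ",
      nrow(object@centroids), " clusters, root '", object@root, "', ",
      object@branchPoints, " branch point(s)\n", sep = "")
})

#' @describeIn TrajectoryResult per-cell pseudotime, named by cell id.
#' @param x a `TrajectoryResult`.
#' @export
pseudotime <- function(x) {
  stopifnot(is(x, "TrajectoryResult"))
  x@pseudotime
}

#' @describeIn TrajectoryResult number of centroid-tree nodes with degree
#'   >= 3.
#' @export
branchPoints <- function(x) {
  stopifnot(is(x, "TrajectoryResult"))
  x@branchPoints
}

#' @describeIn TrajectoryResult per-cell cluster labels.
#' @export
cellClusters <- function(x) {
  stopifnot(is(x, "TrajectoryResult"))
  x@clusters
}
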