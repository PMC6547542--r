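# Synthetic genome, peak landscape and tag counts.  Each generator draws
# from its own child stream of the master seed (see .childSeed) so that any
# stage can be regenerated independently and deterministically.

#' Generate a synthetic TSS annotation
#'
#' Genes are laid out on a fixed grid, one per slot of
#' `chromLength / genesPerChrom` bp, jittered within the slot so that every
#' promoter window (`promoterWindow` bp either side of the TSS) stays inside
#' chromosome bounds and no two windows overlap.  Strands are sampled 50/50.
#'
#' @param config a [SimulationConfig()].
#' @return a width-1 `GRanges` of TSS positions named by gene id (see
#'   [tssAnnotation()]).
#' @examples
#' generateAnnotation(SimulationConfig(seed = 1, nGenes = 10L))
#' @export
generateAnnotation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  n <- config@nGenes
  if (n == 0L)
    return(tssAnnotation(character(), character(), integer()))
  .withSeed(.childSeed(config@seed, "annotation"), {
    perChrom <- rep(n %/% config@nChroms, config@nChroms)
    extra <- n %% config@nChroms
    if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
    w <- config@promoterWindow
    chrom <- character(0); pos <- integer(0)
    for (ci in seq_len(config@nChroms)) {
      k <- perChrom[ci]
      if (k == 0L) next
      spacing <- floor(config@chromLength / k)
      slack <- spacing - 2L * w - 1L
      if (slack < 0)
        stop("cannot place ", k, " genes on a ",
             format(config@chromLength, big.mark = ","),
             " bp chromosome without overlapping promoter windows")
      jitter <- floor(runif(k, 0, slack + 1))
      p <- (seq_len(k) - 1L) * spacing + w + jitter
      chrom <- c(chrom, rep(paste0("chr", ci), k))
      pos <- c(pos, as.integer(p))
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    id <- sprintf("gene_%04d", seq_len(n))
    tssAnnotation(id, chrom, pos, strand)
  })
}

#' Generate the planted peak landscape
#'
#' Places `nPeaksShared + nPeaksTf1Specific + nPeaksTf2Specific +
#' nBackground` non-overlapping peaks of `peakWidth` bp, a fraction
#' `promoterFraction` of each class centred on a TSS and the rest on a
#' distal grid clear of every promoter window.  Truth is recorded in the
#' metadata columns: `class` (shared / tf1_specific / tf2_specific /
#' background), `location` (promoter / distal, by construction) and
#' `accessible` (`TRUE` for all non-background peaks and for a
#' `backgroundAccessibleFraction` of background peaks).
#'
#' @param config a [SimulationConfig()].
#' @param annotation the TSS annotation from [generateAnnotation()].
#' @return a named, position-sorted `GRanges` with truth metadata columns.
#' @export
generatePeakLandscape <- function(config, annotation) {
  stopifnot(is(config, "SimulationConfig"))
  counts <- c(shared = config@nPeaksShared,
              tf1_specific = config@nPeaksTf1Specific,
              tf2_specific = config@nPeaksTf2Specific,
              background = config@nBackground)
  if (sum(counts) == 0L) {
    out <- GRanges()
    mcols(out) <- DataFrame(class = character(), location = character(),
                            accessible = logical())
    return(out)
  }
  .withSeed(.childSeed(config@seed, "peaks"), {
    w <- config@peakWidth
    half <- w %/% 2L
    nProm <- round(counts * config@promoterFraction)
    nDist <- counts - nProm

    chromLevels <- paste0("chr", seq_len(config@nChroms))
    promChrom <- as.character(seqnames(annotation))
    promStart <- pmax(1L, start(annotation) - half)
    if (sum(nProm) > length(promStart))
      stop("capacity error: ", sum(nProm),
           " promoter peaks requested but only ", length(promStart),
           " promoter slots available")

    stride <- 3L * w
    gridStarts <- seq.int(1L, config@chromLength - w, by = stride)
    distChrom <- rep(chromLevels, each = length(gridStarts))
    distStart <- rep(gridStarts, config@nChroms)
    if (length(annotation)) {
      win <- .promoterWindows(annotation, config@promoterWindow)
      cand <- GRanges(factor(distChrom, chromLevels),
                      IRanges(distStart, width = w))
      hit <- unique(queryHits(suppressWarnings(
        findOverlaps(cand, win, ignore.strand = TRUE))))
      if (length(hit)) {
        distChrom <- distChrom[-hit]
        distStart <- distStart[-hit]
      }
    }
    if (sum(nDist) > length(distStart))
      stop("capacity error: ", sum(nDist),
           " distal peaks requested but only ", length(distStart),
           " distal slots available")

    classes <- names(counts)
    promSel <- sample(length(promStart), sum(nProm))
    distSel <- sample(length(distStart), sum(nDist))
    peaks <- GRanges(factor(c(promChrom[promSel], distChrom[distSel]),
                            chromLevels),
                     IRanges(c(promStart[promSel], distStart[distSel]),
                             width = w))
    cls <- c(rep(classes, nProm), rep(classes, nDist))
    loc <- rep(c("promoter", "distal"), c(sum(nProm), sum(nDist)))
    acc <- cls != "background"
    nbg <- sum(cls == "background")
    if (nbg > 0)
      acc[cls == "background"] <-
        runif(nbg) < config@backgroundAccessibleFraction
    mcols(peaks) <- DataFrame(class = cls, location = loc, accessible = acc)
    o <- order(as.character(seqnames(peaks)), start(peaks))
    peaks <- peaks[o]
    names(peaks) <- sprintf("peak_%05d", seq_along(peaks))
    peaks
  })
}

#' Simulate ChIP and ATAC tag counts over a peak landscape
#'
#' Draws negative-binomial counts (Poisson when `dispersion` is 0) for the
#' two ChIP factors and the ATAC assay in every genotype, `nReplicates`
#' columns each.  Expected signal follows the planted truth:
#'
#' * shared peaks carry `meanDepth` for both factors;
#' * factor-specific peaks carry `meanDepth` for their factor and
#'   `meanDepth / effectFold` for the other;
#' * background peaks carry `backgroundDepth` throughout;
#' * in genotypes listed in `nullGenotypes` factor 1 cannot bind and its
#'   counts drop to the background expectation (ChIP input noise, not zero);
#' * in mutant (non wild-type) genotypes a `compensatedFraction` of the
#'   factor-1-specific peaks gains factor-2 signal up to the occupied mean —
#'   the planted de novo acquisitions;
#' * ATAC signal is `meanDepth` at accessible peaks and `backgroundDepth`
#'   elsewhere, identical in expectation across genotypes.
#'
#' @param peaks the truth-annotated landscape from [generatePeakLandscape()].
#' @param config a [SimulationConfig()].
#' @return a raw [TagCountTable()] with one column per
#'   (factor, genotype, replicate); `colData` carries `factor`, `genotype`,
#'   `replicate`; `rowData` carries the peak truth plus the planted
#'   `compensated` flag.
#' @export
simulateTagCounts <- function(peaks, config) {
  stopifnot(is(config, "SimulationConfig"))
  .checkPeakSet(peaks)
  if (length(peaks) == 0L) stop("peak landscape is empty")
  truth <- mcols(peaks)
  if (is.null(truth$class) || is.null(truth$accessible))
    stop("peaks must carry 'class' and 'accessible' truth columns ",
         "(see generatePeakLandscape)")
  if (config@meanDepth <= 0 || config@backgroundDepth < 0)
    stop("meanDepth must be positive and backgroundDepth non-negative")
  .withSeed(.childSeed(config@seed, "tags"), {
    cls <- truth$class
    npk <- length(peaks)
    wt <- config@genotypes[1L]
    spec1 <- which(cls == "tf1_specific")
    nComp <- round(config@compensatedFraction * length(spec1))
    compensated <- logical(npk)
    if (nComp > 0) compensated[sample(spec1, nComp)] <- TRUE

    lowMean <- config@meanDepth / config@effectFold
    baseMu <- function(fac) {
      mu <- rep(config@backgroundDepth, npk)
      if (fac == "atac") {
        mu[truth$accessible] <- config@meanDepth
      } else if (fac == "tf1") {
        mu[cls %in% c("shared", "tf1_specific")] <- config@meanDepth
        mu[cls == "tf2_specific"] <- lowMean
      } else {
        mu[cls %in% c("shared", "tf2_specific")] <- config@meanDepth
        mu[cls == "tf1_specific"] <- lowMean
      }
      mu
    }

    cols <- list(); cd <- list()
    for (fac in c("tf1", "tf2", "atac")) {
      for (gt in config@genotypes) {
        mu <- baseMu(fac)
        if (fac == "tf1" && gt %in% config@nullGenotypes)
          mu <- rep(config@backgroundDepth, npk)
        if (fac == "tf2" && gt != wt)
          mu[compensated] <- config@meanDepth
        for (r in seq_len(config@nReplicates)) {
          nm <- paste(fac, gt, paste0("rep", r), sep = "_")
          cols[[nm]] <- .rcounts(npk, mu, config@dispersion)
          cd[[nm]] <- c(fac, gt, r)
        }
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- names(peaks)
    cdf <- DataFrame(factor = unname(vapply(cd, `[`, "", 1L)),
                     genotype = unname(vapply(cd, `[`, "", 2L)),
                     replicate = as.integer(vapply(cd, `[`, "", 3L)),
                     row.names = names(cols))
    tab <- TagCountTable(m, colData = cdf)
    rowData(tab) <- cbind(truth, DataFrame(compensated = compensated))
    tab
  })
}
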