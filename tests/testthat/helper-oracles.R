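# Independent brute-force oracles and small fixture builders.  The oracles
# deliberately use naive, element-by-element implementations so they share
# no code path with the package functions they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(SingleCellExperiment)
  library(S4Vectors)
})

# 0-based half-open coordinates of a peak set, as a plain data.frame.
peakDf <- function(ps) {
  data.frame(id = names(ps), chrom = as.character(seqnames(ps)),
             start0 = start(ps) - 1L, end0 = end(ps),
             stringsAsFactors = FALSE)
}

# All-pairs overlap scan on half-open intervals.
bfOverlapPairs <- function(a, b, minOverlap = 1L) {
  da <- peakDf(a); db <- peakDf(b)
  out <- list()
  for (i in seq_len(nrow(da))) for (j in seq_len(nrow(db))) {
    if (da$chrom[i] != db$chrom[j]) next
    ov <- min(da$end0[i], db$end0[j]) - max(da$start0[i], db$start0[j])
    if (ov >= minOverlap)
      out[[length(out) + 1L]] <- data.frame(id_a = da$id[i],
                                            id_b = db$id[j])
  }
  if (!length(out))
    return(data.frame(id_a = character(), id_b = character()))
  out <- do.call(rbind, out)
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

# Per-peak promoter/distal call by scanning every TSS window.
bfAnnotate <- function(ps, tss, window) {
  dp <- peakDf(ps)
  pos0 <- start(tss) - 1L
  chromT <- as.character(seqnames(tss))
  out <- setNames(rep("distal", nrow(dp)), dp$id)
  for (i in seq_len(nrow(dp))) {
    for (j in seq_along(tss)) {
      if (dp$chrom[i] != chromT[j]) next
      ws <- pos0[j] - window; we <- pos0[j] + window  # half-open window
      if (min(dp$end0[i], we) - max(dp$start0[i], ws) >= 1)
        out[i] <- "promoter"
    }
  }
  out
}

# Naive two-strand PWM scan enumerating every window position.
bfScanPWM <- function(sequence, pwm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  probs <- pwm@probs; bg <- pwm@background
  L <- nrow(probs)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(chars)
  thr <- if (!is.na(pwm@scoreThreshold)) pwm@scoreThreshold
         else 0.8 * pwmMaxScore(pwm)
  hits <- list()
  if (n >= L) for (off in 0:(n - L)) {
    win <- chars[(off + 1):(off + L)]
    if (any(!win %in% names(comp))) next
    sF <- 0; sR <- 0
    for (j in 1:L) {
      bF <- match(win[j], c("A", "C", "G", "T"))
      sF <- sF + log2(probs[j, bF] / bg[bF])
      # minus strand: position j of the motif aligns to the complement of
      # the (L + 1 - j)-th base of the window
      bR <- match(comp[win[L + 1 - j]], c("A", "C", "G", "T"))
      sR <- sR + log2(probs[j, bR] / bg[bR])
    }
    if (!is.na(sF) && sF >= thr)
      hits[[length(hits) + 1L]] <- data.frame(offset = off, strand = "+",
                                              score = sF)
    if (!is.na(sR) && sR >= thr)
      hits[[length(hits) + 1L]] <- data.frame(offset = off, strand = "-",
                                              score = sR)
  }
  if (!length(hits))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# Venn region counts by explicit set algebra (intersect/setdiff), a
# different route from the package's membership-pattern enumeration.
bfVenn <- function(sets) {
  nm <- names(sets)
  sets <- lapply(sets, unique)
  out <- integer(0)
  if (length(sets) == 2L) {
    ab <- intersect(sets[[1]], sets[[2]])
    out[paste0(nm[1], "_only")] <- length(setdiff(sets[[1]], sets[[2]]))
    out[paste0(nm[2], "_only")] <- length(setdiff(sets[[2]], sets[[1]]))
    out[paste(nm, collapse = "&")] <- length(ab)
  } else {
    abc <- Reduce(intersect, sets)
    for (i in 1:3) {
      rest <- unlist(sets[-i])
      out[paste0(nm[i], "_only")] <- length(setdiff(sets[[i]], rest))
    }
    for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
      third <- setdiff(1:3, pr)
      out[paste(nm[pr], collapse = "&")] <-
        length(setdiff(intersect(sets[[pr[1]]], sets[[pr[2]]]),
                       sets[[third]]))
    }
    out[paste(nm, collapse = "&")] <- length(abc)
  }
  out
}

# Textbook Pearson correlation.
bfPearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Two-sided Fisher exact p by hypergeometric enumeration.
bfFisherP <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Random peak set over a couple of chromosomes.
randomPeakSet <- function(n, prefix = "p", maxPos = 5000L,
                          maxWidth = 120L) {
  start <- sample.int(maxPos, n, replace = TRUE)
  width <- sample.int(maxWidth, n, replace = TRUE)
  peakSet(sample(c("chr1", "chr2"), n, replace = TRUE),
          start, start + width, id = paste0(prefix, seq_len(n)))
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Small, fast simulation configs used across test files.
smallConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(nGenes = 120L, nPeaksShared = 60L, nPeaksTf1Specific = 30L,
         nPeaksTf2Specific = 30L, nBackground = 20L,
         nCellsPerGenotype = 120L),
    list(...))
  do.call(SimulationConfig, c(list(seed = seed), args))
}
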