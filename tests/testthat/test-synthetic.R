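test_that("annotation generation is deterministic and respects bounds", {
  cfg <- SimulationConfig(seed = 2, nGenes = 0L)
  expect_length(generateAnnotation(cfg), 0)

  cfg <- SimulationConfig(seed = 2, nChroms = 1L, chromLength = 1e6,
                          nGenes = 100L)
  a1 <- generateAnnotation(cfg)
  a2 <- generateAnnotation(cfg)
  expect_identical(a1, a2)
  # every promoter window inside chromosome bounds, checked exhaustively
  w <- 1000L
  pos0 <- start(a1) - 1L
  expect_true(all(pos0 - w >= 0))
  expect_true(all(pos0 + w <= 1e6))
  # windows must not overlap each other
  o <- order(pos0)
  expect_true(all(diff(pos0[o]) >= 2 * w))
  expect_true(all(sort(unique(as.character(strand(a1)))) %in% c("+", "-")))

  tiny <- SimulationConfig(seed = 2, nChroms = 1L, chromLength = 10000,
                           nGenes = 50L)
  expect_error(generateAnnotation(tiny), "cannot place")
})

test_that("peak landscape realizes the requested class histogram", {
  cfg0 <- SimulationConfig(seed = 4, nPeaksShared = 0L,
                           nPeaksTf1Specific = 0L,
                           nPeaksTf2Specific = 0L, nBackground = 0L)
  expect_length(generatePeakLandscape(cfg0, generateAnnotation(cfg0)), 0)

  cfg <- SimulationConfig(seed = 4, nGenes = 60L, nPeaksShared = 10L,
                          nPeaksTf1Specific = 5L, nPeaksTf2Specific = 5L,
                          nBackground = 5L)
  peaks <- generatePeakLandscape(cfg, generateAnnotation(cfg))
  expect_length(peaks, 25)
  expect_equal(as.vector(table(mcols(peaks)$class)[c(
    "shared", "tf1_specific", "tf2_specific", "background")]),
    c(10, 5, 5, 5))
  # no two emitted intervals overlap: pairwise scan
  expect_equal(nrow(bfOverlapPairs(peaks, peaks)), length(peaks))
})

test_that("tag counts realize planted expectations and determinism", {
  cfg <- smallConfig(6, effectFold = 1, dispersion = 0, meanDepth = 40)
  peaks <- generatePeakLandscape(cfg, generateAnnotation(cfg))
  tags <- simulateTagCounts(peaks, cfg)
  cnt <- assay(tags, "counts")
  occ <- rowData(tags)$class != "background"
  # effectFold 1: both factors share the same expectation at occupied peaks
  m1 <- mean(cnt[occ, "tf1_WT_rep1"])
  m2 <- mean(cnt[occ, "tf2_WT_rep1"])
  expect_lt(abs(m1 - m2) / 40, 0.05)

  # Monte-Carlo: sample mean over 2,000 peaks within 5% of meanDepth 50
  big <- SimulationConfig(seed = 8, meanDepth = 50)
  bp <- generatePeakLandscape(big, generateAnnotation(big))
  bt <- simulateTagCounts(bp, big)
  bc <- assay(bt, "counts")
  shared <- rowData(bt)$class == "shared"
  expect_lt(abs(mean(bc[shared, "tf1_WT_rep1"]) - 50) / 50, 0.05)

  t1 <- simulateTagCounts(peaks, cfg)
  expect_identical(assay(t1, "counts"), cnt)
  t2 <- simulateTagCounts(peaks, smallConfig(7, effectFold = 1,
                                             dispersion = 0,
                                             meanDepth = 40))
  expect_false(identical(assay(t2, "counts"), cnt))
})

test_that("binding-null and compensation structure is planted", {
  cfg <- smallConfig(9, dispersion = 0)
  tags <- simulateTagCounts(
    generatePeakLandscape(cfg, generateAnnotation(cfg)), cfg)
  cnt <- assay(tags, "counts")
  rd <- rowData(tags)
  occ <- rd$class %in% c("shared", "tf1_specific")
  # factor 1 collapses to background level in the binding-null genotype
  expect_lt(mean(cnt[occ, "tf1_mutA_rep1"]), 10)
  expect_gt(mean(cnt[occ, "tf1_WT_rep1"]), 80)
  # compensated factor-1-specific peaks gain factor-2 signal in the mutant
  comp <- rd$class == "tf1_specific" & rd$compensated
  uncomp <- rd$class == "tf1_specific" & !rd$compensated
  expect_gt(mean(cnt[comp, "tf2_mutA_rep1"]), 80)
  expect_lt(mean(cnt[uncomp, "tf2_mutA_rep1"]), 40)
})

test_that("planted motif placements match the sequences exactly", {
  cfg <- smallConfig(12)
  peaks <- generatePeakLandscape(cfg, generateAnnotation(cfg))
  sm <- generateSequencesWithMotifs(peaks, cfg)
  cons <- pwmConsensus(spLikePWM())
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  expect_gt(nrow(sm$placements), 0)
  expect_true(any(sm$placements$strand == "-"))
  for (i in seq_len(nrow(sm$placements))) {
    s <- as.character(sm$sequences[[sm$placements$peak[i]]])
    piece <- substr(s, sm$placements$offset[i] + 1,
                    sm$placements$offset[i] + nchar(cons))
    expect_identical(piece, if (sm$placements$strand[i] == "+") cons
                            else rc)
  }
  # planted instances never overlap
  byPeak <- split(sm$placements, sm$placements$peak)
  for (pl in byPeak) {
    pl <- pl[order(pl$offset), ]
    if (nrow(pl) > 1)
      expect_true(all(diff(pl$offset) >= nchar(cons)))
  }
})

test_that("zero motif rate leaves sequences free of the consensus", {
  cfg <- smallConfig(13, motifRatePromoter = 0, motifRateDistal = 0)
  peaks <- generatePeakLandscape(cfg, generateAnnotation(cfg))
  sm <- generateSequencesWithMotifs(peaks, cfg)
  expect_equal(nrow(sm$placements), 0)
  cons <- pwmConsensus(spLikePWM())
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  hits <- vapply(as.character(sm$sequences), function(s)
    grepl(cons, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), TRUE)
  expect_false(any(hits))
})

test_that("expression realizes planted folds and group proportions", {
  # all genes unchanged, zero noise: mutants identical to WT
  cfg <- smallConfig(14, expressionNoiseSd = 0,
                     groupProportions = c(rep(0, 8), 1))
  anno <- generateAnnotation(cfg)
  e <- simulateExpression(anno, cfg)
  m <- assay(e, "expr")
  expect_equal(m[, "ESC_mutA_rep1"], m[, "ESC_WT_rep1"])
  expect_equal(m[, "HE2_mutB_rep2"], m[, "HE2_WT_rep2"])

  # all genes "up in mutant A only" at fold 4, zero noise
  cfgA <- smallConfig(14, expressionNoiseSd = 0, expressionFold = 4,
                      groupProportions = c(0, 1, rep(0, 7)))
  eA <- simulateExpression(anno, cfgA)
  mA <- assay(eA, "expr")
  expect_equal(mA[, "Flk1_mutA_rep1"] / mA[, "Flk1_WT_rep1"],
               setNames(rep(4, nrow(mA)), rownames(mA)))
  expect_equal(mA[, "Flk1_mutB_rep1"] / mA[, "Flk1_WT_rep1"],
               setNames(rep(1, nrow(mA)), rownames(mA)))

  # group histogram follows groupProportions within multinomial error
  big <- SimulationConfig(seed = 15, nGenes = 5000L, nChroms = 8L)
  eb <- simulateExpression(generateAnnotation(big), big)
  tab <- table(rowData(eb)$group)
  expect_equal(unname(tab["unchanged"]) / 5000, 0.6, tolerance = 0.05)
  for (g in as.character(1:8))
    expect_equal(unname(tab[g]) / 5000, 0.05, tolerance = 0.25)
  expect_error(simulateExpression(anno, smallConfig(1, exprReplicates = 1L)),
               "replicates")
})

test_that("single-cell truth matches the requested topology", {
  cfg <- smallConfig(16, trajectoryTopology = "bifurcating",
                     extraClusterInMutant = FALSE)
  cells <- simulateSingleCells(cfg)
  expect_named(cells, c("WT", "mutA"))
  expect_equal(sort(unique(colData(cells$WT)$branch)),
               c("armA", "armB", "trunk"))
  expect_setequal(unique(colData(cells$WT)$trueCluster),
                  unique(colData(cells$mutA)$trueCluster))

  withExtra <- smallConfig(16, extraClusterInMutant = TRUE)
  cells2 <- simulateSingleCells(withExtra)
  expect_false("extra" %in% colData(cells2$WT)$trueCluster)
  expect_true("extra" %in% colData(cells2$mutA)$trueCluster)
  expect_error(simulateSingleCells(smallConfig(1, nCellsPerGenotype = 5L)),
               "20 cells")
})

test_that("noiseless linear cells order along the first principal axis", {
  cfg <- smallConfig(17, trajectoryTopology = "linear", scNoiseSd = 0,
                     scPoisson = FALSE, scMarkersPerCluster = 0L,
                     extraClusterInMutant = FALSE)
  sce <- preprocessCells(simulateSingleCells(cfg)$WT)
  pc1 <- prcomp(t(assay(sce, "logcounts")))$x[, 1]
  rho <- cor(pc1, colData(sce)$latentTime, method = "spearman")
  expect_equal(abs(rho), 1)
})

test_that("generators are reproducible under one master seed", {
  cfg <- smallConfig(18)
  a1 <- generateAnnotation(cfg); a2 <- generateAnnotation(cfg)
  expect_identical(a1, a2)
  p1 <- generatePeakLandscape(cfg, a1)
  p2 <- generatePeakLandscape(cfg, a2)
  expect_identical(p1, p2)
  s1 <- generateSequencesWithMotifs(p1, cfg)
  s2 <- generateSequencesWithMotifs(p2, cfg)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(s1$placements, s2$placements)
  e1 <- simulateExpression(a1, cfg); e2 <- simulateExpression(a1, cfg)
  expect_identical(assay(e1, "expr"), assay(e2, "expr"))
  c1 <- simulateSingleCells(cfg); c2 <- simulateSingleCells(cfg)
  expect_identical(assay(c1$WT, "counts"), assay(c2$WT, "counts"))
})
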