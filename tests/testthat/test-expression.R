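# small expression SE builder: values is genes x (stage x genotype), one
# replicate per condition unless reps > 1
exprSE <- function(values, stages, genotypes, reps = 2) {
  cols <- expand.grid(rep = seq_len(reps), genotype = genotypes,
                      stage = stages, stringsAsFactors = FALSE)
  m <- matrix(0, nrow(values), nrow(cols))
  for (i in seq_len(nrow(cols))) {
    key <- paste(cols$stage[i], cols$genotype[i], sep = "_")
    m[, i] <- values[, key]
  }
  dimnames(m) <- list(rownames(values),
                      paste(cols$stage, cols$genotype,
                            paste0("rep", cols$rep), sep = "_"))
  SummarizedExperiment(
    assays = list(expr = m),
    colData = DataFrame(stage = cols$stage, genotype = cols$genotype,
                        replicate = cols$rep, row.names = colnames(m)))
}

test_that("selectDifferential applies the fold rule per stage", {
  v <- matrix(10, 3, 6,
              dimnames = list(paste0("g", 1:3),
                              paste(rep(c("ESC", "HE1"), each = 3),
                                    c("WT", "mutA", "mutB"), sep = "_")))
  se0 <- exprSE(v, c("ESC", "HE1"), c("WT", "mutA", "mutB"))
  expect_length(selectDifferential(se0), 0)
  v["g2", "HE1_mutA"] <- 40   # 4-fold up at one stage only
  se <- exprSE(v, c("ESC", "HE1"), c("WT", "mutA", "mutB"))
  expect_equal(selectDifferential(se), "g2")
  # monotone in the threshold: raising it never adds genes
  v["g3", "ESC_mutB"] <- 25
  se2 <- exprSE(v, c("ESC", "HE1"), c("WT", "mutA", "mutB"))
  lo <- selectDifferential(se2, foldThreshold = 2)
  hi <- selectDifferential(se2, foldThreshold = 3)
  expect_true(all(hi %in% lo))
})

test_that("differential selection recovers the planted gene set", {
  cfg <- smallConfig(31)
  anno <- generateAnnotation(cfg)
  e <- simulateExpression(anno, cfg)
  de <- selectDifferential(e)
  truth <- rowData(e)$group != "unchanged"
  sens <- mean(rownames(e)[truth] %in% de)
  spec <- mean(!rownames(e)[!truth] %in% de)
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("row Z-scores are centred, scaled and guarded", {
  z <- rowZscore(matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(as.vector(rowZscore(matrix(5, 1, 4))), rep(0, 4))
  set.seed(32)
  m <- matrix(rnorm(60, 10), 6, 10)
  Z <- rowZscore(m)
  expect_equal(unname(rowMeans(Z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(Z^2))), rep(1, 6), tolerance = 1e-12)
})

test_that("covariance clustering separates orthogonal patterns", {
  skip_if_not_installed("mclust")
  set.seed(33)
  up <- seq(-1, 1, length.out = 10)
  z <- rbind(matrix(rep(up, 20), 20, byrow = TRUE),
             matrix(rep(-up, 20), 20, byrow = TRUE))
  rownames(z) <- paste0("g", 1:40)
  res <- clusterCovariant(z, 2)
  truth <- rep(1:2, each = 20)
  expect_equal(mclust::adjustedRandIndex(res$clusters, truth), 1)
  expect_equal(dim(res$profiles), c(2L, 10L))
  # boundary cuts
  expect_true(all(clusterCovariant(z, 1)$clusters == 1))
  expect_length(unique(clusterCovariant(z, 40)$clusters), 40)
  expect_error(clusterCovariant(z, 41), "between")
})

test_that("the 8-group map honours the shared and reciprocal anchors", {
  grid <- expand.grid(dirA = c("up", "unchanged", "down"),
                      dirB = c("up", "unchanged", "down"),
                      stringsAsFactors = FALSE)
  fold <- function(d) c(up = 4, unchanged = 1, down = 0.25)[d]
  v <- matrix(10, nrow(grid), 3,
              dimnames = list(paste0("g", seq_len(nrow(grid))),
                              paste0("ESC_", c("WT", "mutA", "mutB"))))
  v[, "ESC_mutA"] <- 10 * fold(grid$dirA)
  v[, "ESC_mutB"] <- 10 * fold(grid$dirB)
  se <- exprSE(v, "ESC", c("WT", "mutA", "mutB"))
  ga <- assignDirectionGroups(se, "ESC")
  # grid order (dirA fastest): (u,u),(un,u),(d,u),(u,un),(un,un),(d,un),
  # (u,d),(un,d),(d,d)
  want <- c("1", "3", "5", "2", "unchanged", "7", "4", "6", "8")
  expect_equal(ga$group, want)
  # both-up is Group 1, both-down Group 8, reciprocal pairs 4 and 5
  expect_equal(ga$group[grid$dirA == "up" & grid$dirB == "up"], "1")
  expect_equal(ga$group[grid$dirA == "down" & grid$dirB == "down"], "8")
  expect_equal(ga$group[grid$dirA == "up" & grid$dirB == "down"], "4")
  expect_equal(ga$group[grid$dirA == "down" & grid$dirB == "up"], "5")
  expect_error(assignDirectionGroups(se, "Flk1"), "unknown cell type")
})

test_that("grouping is exhaustive, exclusive and mutant-swap symmetric", {
  set.seed(34)
  for (rep in 1:4) {
    v <- matrix(2^runif(90, 0, 6), 30, 3,
                dimnames = list(paste0("g", 1:30),
                                paste0("ESC_", c("WT", "mutA", "mutB"))))
    se <- exprSE(v, "ESC", c("WT", "mutA", "mutB"))
    ga <- assignDirectionGroups(se, "ESC")
    # exhaustive and exclusive; ungrouped iff unchanged in both mutants
    expect_true(all(ga$group %in% c(as.character(1:8), "unchanged")))
    expect_identical(ga$group == "unchanged",
                     ga$dirA == "unchanged" & ga$dirB == "unchanged")
    # swapping the mutants maps 1<->1, 8<->8, 4<->5
    sw <- assignDirectionGroups(se, "ESC",
                                mutants = c("mutB", "mutA"))
    map <- c("1" = "1", "2" = "3", "3" = "2", "4" = "5", "5" = "4",
             "6" = "7", "7" = "6", "8" = "8",
             "unchanged" = "unchanged")
    expect_identical(unname(map[ga$group]), sw$group)
  }
})

test_that("noiseless planted groups are recovered exactly", {
  cfg <- smallConfig(35, expressionNoiseSd = 0)
  e <- simulateExpression(generateAnnotation(cfg), cfg)
  for (st in c("ESC", "Prog")) {
    ga <- assignDirectionGroups(e, st)
    expect_identical(ga$group, rowData(e)$group)
  }
})

test_that("peak-to-gene targets match a brute-force distance scan", {
  tss <- tssAnnotation(c("g1", "g2"), c("chr1", "chr1"), c(5000, 20000))
  atTss <- peakSet("chr1", 4950, 5050, id = "pk1")
  expect_equal(mapPeaksToGenes(atTss, tss), list(g1 = "pk1"))
  far <- peakSet("chr1", 10000, 10100, id = "pk2")
  expect_length(mapPeaksToGenes(far, tss), 0)
  set.seed(36)
  ps <- randomPeakSet(120)
  tss <- tssAnnotation(paste0("g", 1:25),
                       sample(c("chr1", "chr2"), 25, replace = TRUE),
                       sample.int(5000, 25))
  got <- mapPeaksToGenes(ps, tss, 500)
  dp <- peakDf(ps)
  pos0 <- start(tss) - 1L
  for (j in seq_along(tss)) {
    hits <- character()
    for (i in seq_len(nrow(dp))) {
      if (dp$chrom[i] != as.character(seqnames(tss))[j]) next
      gap <- max(dp$start0[i] - pos0[j], pos0[j] - (dp$end0[i] - 1L), 0)
      if (gap <= 500) hits <- c(hits, dp$id[i])
    }
    if (length(hits))
      expect_setequal(got[[names(tss)[j]]], hits)
    else expect_false(names(tss)[j] %in% names(got))
  }
})

test_that("Venn region counts match explicit set algebra", {
  a <- paste0("g", 1:10)
  same <- overlapTargets(list(A = a, B = a))
  expect_equal(unname(same["A&B"]), 10)
  expect_equal(unname(same["A_only"] + same["B_only"]), 0)
  disj <- overlapTargets(list(A = a, B = paste0("h", 1:5)))
  expect_equal(unname(disj["A&B"]), 0)
  expect_equal(sum(disj), 15)
  set.seed(37)
  for (rep in 1:5) {
    sets <- list(A = sample(letters, 12), B = sample(letters, 8),
                 C = sample(letters, 15))
    got <- overlapTargets(sets)
    want <- bfVenn(sets)
    expect_equal(got[names(want)], want)
    expect_equal(sum(got), length(unique(unlist(sets))))
  }
  expect_error(overlapTargets(list(a = "x")), "2 or 3")
})
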