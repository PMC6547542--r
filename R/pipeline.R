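# End-to-end orchestration: materialize a synthetic dataset as text files,
# and run every analysis stage over a dataset directory.

#' Write a complete synthetic dataset to disk
#'
#' Generates annotation, peak landscape, tag counts, peak sequences, bulk
#' expression and single-cell matrices from one configuration and writes
#' them — together with every truth table and the configuration itself — as
#' plain-text files.  Running [runPipeline()] on the resulting directory is
#' the package's canonical integration test.
#'
#' @param config a [SimulationConfig()].
#' @param dir output directory (created if missing).
#' @return the manifest: a named character vector of written files,
#'   invisibly.
#' @export
writeDataset <- function(config, dir) {
  stopifnot(is(config, "SimulationConfig"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  cfg <- lapply(slotNames("SimulationConfig"), function(s) slot(config, s))
  names(cfg) <- slotNames("SimulationConfig")
  yaml::write_yaml(cfg, p("config.yaml"))

  anno <- generateAnnotation(config)
  writeTss(anno, p("annotation.tsv"))

  peaks <- generatePeakLandscape(config, anno)
  writeBed(peaks, p("peaks.bed"))
  writeBed(peaks[mcols(peaks)$accessible], p("atac_peaks.bed"))

  tags <- simulateTagCounts(peaks, config)
  writeTagCounts(tags, p("tag_counts.tsv"))
  truth <- data.frame(peak_id = names(peaks),
                      as.data.frame(rowData(tags)), check.names = FALSE)
  write.table(truth, p("truth_peaks.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  pwm <- spLikePWM()
  writePWM(pwm, p("motif.pwm"))
  seqs <- generateSequencesWithMotifs(peaks, config, pwm)
  writeXStringSet(seqs$sequences, p("sequences.fasta"))
  write.table(seqs$placements, p("truth_motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  expr <- simulateExpression(anno, config)
  writeExpressionTable(expr, p("expression.tsv"))
  write.table(data.frame(gene_id = rownames(expr),
                         as.data.frame(rowData(expr)), check.names = FALSE),
              p("truth_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  cells <- simulateSingleCells(config)
  for (gt in names(cells))
    writeCellMatrix(cells[[gt]], p(sprintf("cells_%s_counts.tsv", gt)),
                    p(sprintf("cells_%s_meta.tsv", gt)))

  files <- c("config.yaml", "annotation.tsv", "peaks.bed", "atac_peaks.bed",
             "tag_counts.tsv", "truth_peaks.tsv", "motif.pwm",
             "sequences.fasta", "truth_motifs.tsv", "expression.tsv",
             "truth_genes.tsv",
             as.vector(t(outer(names(cells), c("counts", "meta"),
                               function(g, w)
                                 sprintf("cells_%s_%s.tsv", g, w)))))
  invisible(setNames(file.path(dir, files), files))
}

#' Run the full comparative-occupancy pipeline over a dataset directory
#'
#' Executes, in order: high-confidence (ATAC-overlap) peak filtering, tag
#' normalisation, accessibility correlation and differential sites,
#' shared/specific classification, de novo acquisition/loss detection,
#' motif counting/distributions/enrichment, differential-gene selection,
#' covariance clustering, directional 8-group assignment, peak-to-gene
#' target mapping, Venn overlaps and — when single-cell inputs are present —
#' clustering, pseudotime and the genotype comparison.  Every intermediate
#' is written as TSV/BED/JSON under `outDir`, plus a machine-readable
#' `summary.json`.
#'
#' @param dataDir a dataset directory as produced by [writeDataset()] (the
#'   file names double as the expected layout for real data).
#' @param outDir output directory (created if missing).
#' @param foldThreshold inclusive fold-change threshold used throughout.
#' @param pseudocount pseudocount on the normalized scale.
#' @param normTarget tags per sample after normalisation.
#' @param promoterWindow promoter half-width in bp (also the target-mapping
#'   distance).
#' @param minExpr expression floor.
#' @param K covariance cluster count (capped at the number of selected
#'   genes).
#' @param d,kCells principal components and cluster count for the
#'   single-cell stage.
#' @param rootCluster root cluster label for pseudotime; `NULL` picks the
#'   cluster with the lowest mean `latentTime` when the cell metadata
#'   carries one (as synthetic datasets do) and otherwise skips the
#'   trajectory stage with a message.
#' @return the summary list, invisibly (also written as `summary.json`).
#' @export
runPipeline <- function(dataDir, outDir,
                        foldThreshold = 2, pseudocount = 1,
                        normTarget = 1e7, promoterWindow = 1000L,
                        minExpr = 1, K = 13L, d = 10L, kCells = NULL,
                        rootCluster = NULL) {
  if (!dir.exists(dataDir)) stop("no such dataset directory: ", dataDir)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  p <- function(f) file.path(dataDir, f)
  o <- function(f) file.path(outDir, f)
  need <- function(f) {
    if (!file.exists(p(f))) stop("stage input missing: ", f)
    p(f)
  }
  summary <- list(parameters = list(
    foldThreshold = foldThreshold, pseudocount = pseudocount,
    normTarget = normTarget, promoterWindow = promoterWindow,
    minExpr = minExpr, K = K, d = d))

  ## -- peaks and filtering ------------------------------------------------
  peaks <- readBed(need("peaks.bed"))
  atac <- readBed(need("atac_peaks.bed"))
  anno <- readTss(need("annotation.tsv"))
  hc <- filterHighConfidence(peaks, atac)
  writeBed(hc, o("high_confidence.bed"))
  summary$peaks <- list(n_input = length(peaks),
                        n_high_confidence = length(hc))

  ## -- tag counts: normalisation, correlation, differential, classes -----
  tags <- readTagCounts(need("tag_counts.tsv"))
  tags <- tags[names(hc), ]
  norm <- normalizeTags(tags, normTarget)
  cd <- colData(norm)
  genotypes <- unique(cd$genotype)
  wt <- genotypes[1L]
  mutants <- setdiff(genotypes, wt)
  samplesOf <- function(fac, gt) rownames(cd)[cd$factor == fac &
                                              cd$genotype == gt]

  atacCols <- rownames(cd)[cd$factor == "atac"]
  corM <- correlationMatrix(norm[, atacCols])
  write.table(data.frame(sample = rownames(corM), corM,
                         check.names = FALSE),
              o("atac_correlation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  cnt <- assay(norm, "counts")
  atacMean <- function(gt) rowMeans(cnt[, samplesOf("atac", gt),
                                        drop = FALSE])
  diffAtac <- lapply(mutants, function(mt)
    differentialSites(atacMean(wt), setNames(atacMean(mt),
                                             names(atacMean(wt))),
                      foldThreshold, pseudocount))
  names(diffAtac) <- mutants
  summary$differential_accessibility <- lapply(diffAtac, function(x)
    list(n_gained = length(x$gained), n_lost = length(x$lost)))

  classes <- classifySharedSpecific(norm, samplesOf("tf1", wt),
                                    samplesOf("tf2", wt),
                                    foldThreshold, pseudocount)
  write.table(data.frame(peak_id = rownames(classes),
                         as.data.frame(classes), check.names = FALSE),
              o("classification.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  summary$classification <- as.list(metadata(classes)$summary)

  spec1 <- rownames(classes)[classes$label == "tf1_specific"]
  denovo <- list()
  for (mt in mutants) {
    dn <- detectDeNovo(norm, spec1, samplesOf("tf2", wt),
                       samplesOf("tf2", mt), foldThreshold, pseudocount)
    write.table(data.frame(peak_id = rownames(dn), as.data.frame(dn),
                           check.names = FALSE),
                o(sprintf("denovo_%s.tsv", mt)), sep = "\t",
                quote = FALSE, row.names = FALSE)
    denovo[[mt]] <- as.list(metadata(dn)$summary)
  }
  summary$de_novo <- denovo

  ranked <- rankMatrix(norm, samplesOf("tf1", wt)[1L])
  writeTagCounts(ranked, o("ranked_tags.tsv"))

  ## -- motifs -------------------------------------------------------------
  if (file.exists(p("sequences.fasta")) && file.exists(p("motif.pwm"))) {
    seqs <- readDNAStringSet(p("sequences.fasta"))
    pwms <- readPWM(p("motif.pwm"))
    mcnt <- countMotifsPerPeak(seqs[names(hc)], pwms)
    write.table(data.frame(peak_id = rownames(mcnt), mcnt,
                           check.names = FALSE),
                o("motif_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    loc <- annotateLocation(hc, anno, promoterWindow)
    labels <- setNames(classes$label, rownames(classes))
    dist <- motifCountDistribution(mcnt, labels, loc)
    write.table(dist, o("motif_distribution.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    shared <- rownames(classes)[classes$label == "shared"]
    if (length(spec1) && length(shared)) {
      enr <- motifEnrichment(mcnt, spec1, shared)
      write.table(enr, o("motif_enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    summary$motifs <- list(
      n_scanned = nrow(mcnt),
      mean_promoter = mean(mcnt[loc[rownames(mcnt)] == "promoter", 1L]),
      mean_distal = mean(mcnt[loc[rownames(mcnt)] == "distal", 1L]))
  }

  ## -- bulk expression ----------------------------------------------------
  expr <- readExpressionTable(need("expression.tsv"))
  wtExpr <- unique(colData(expr)$genotype)[1L]
  de <- selectDifferential(expr, foldThreshold, minExpr, wtExpr)
  writeLines(de, o("differential_genes.txt"))
  summary$expression <- list(n_genes = nrow(expr),
                             n_differential = length(de))
  groupsPerStage <- list()
  if (length(de) >= 2L) {
    z <- rowZscore(log2(assay(expr, "expr")[de, , drop = FALSE] + 1))
    cc <- clusterCovariant(z, min(K, length(de)))
    write.table(data.frame(gene_id = names(cc$clusters),
                           cluster = cc$clusters),
                o("covariance_clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(cluster = rownames(cc$profiles), cc$profiles,
                           check.names = FALSE),
                o("cluster_profiles.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (st in unique(colData(expr)$stage)) {
      ga <- assignDirectionGroups(expr, st, foldThreshold, minExpr, wtExpr)
      write.table(data.frame(gene_id = rownames(ga), as.data.frame(ga),
                             check.names = FALSE),
                  o(sprintf("groups_%s.tsv", st)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      groupsPerStage[[st]] <- table(ga$group)
    }
    summary$groups <- lapply(groupsPerStage, as.list)
  }

  targets <- if (length(anno)) mapPeaksToGenes(hc, anno, promoterWindow)
             else list()
  write.table(data.frame(gene_id = names(targets),
                         n_peaks = lengths(targets),
                         peaks = vapply(targets, paste, "",
                                        collapse = ",")),
              o("targets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(de) && length(targets)) {
    stage1 <- unique(colData(expr)$stage)[1L]
    ga <- assignDirectionGroups(expr, stage1, foldThreshold, minExpr,
                                wtExpr)
    up <- rownames(ga)[ga$dirA == "up"]
    down <- rownames(ga)[ga$dirA == "down"]
    venn <- overlapTargets(list(targets = names(targets), up = up,
                                down = down))
    summary$venn <- as.list(venn)
  }

  ## -- single cells -------------------------------------------------------
  cellFiles <- list.files(dataDir, "^cells_.*_counts\\.tsv$")
  if (length(cellFiles) >= 2L) {
    gts <- sub("^cells_(.*)_counts\\.tsv$", "\\1", cellFiles)
    res <- list(); sces <- list()
    for (gt in gts) {
      sce <- readCellMatrix(p(sprintf("cells_%s_counts.tsv", gt)),
                            p(sprintf("cells_%s_meta.tsv", gt)))
      sce <- preprocessCells(sce)
      kk <- if (is.null(kCells) && !is.null(colData(sce)$trueCluster))
        length(unique(colData(sce)$trueCluster))
      else if (is.null(kCells)) 4L else kCells
      sce <- reduceAndCluster(sce, d, kk)
      root <- rootCluster
      if (is.null(root) && !is.null(colData(sce)$latentTime)) {
        mt <- tapply(colData(sce)$latentTime, colData(sce)$cluster, mean)
        root <- names(which.min(mt))
      }
      if (is.null(root)) {
        message("no root cluster available; skipping trajectory for ", gt)
        next
      }
      tr <- pseudotimeOrder(sce, root)
      write.table(data.frame(cell_id = colnames(sce),
                             cluster = as.character(cellClusters(tr)),
                             pseudotime = pseudotime(tr)),
                  o(sprintf("trajectory_%s.tsv", gt)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      res[[gt]] <- tr; sces[[gt]] <- sce
    }
    if (length(res) >= 2L) {
      g1 <- names(res)[1L]; g2 <- names(res)[2L]
      cmp <- compareGenotypes(res[[g1]], sces[[g1]], res[[g2]], sces[[g2]])
      jsonlite::write_json(
        list(genotypes = c(g1, g2),
             clusterCountDiff = cmp$clusterCountDiff,
             specificA = cmp$specificA, specificB = cmp$specificB,
             branchPoints = c(cmp$branchPointsA, cmp$branchPointsB),
             matches = cmp$matches),
        o("genotype_comparison.json"), auto_unbox = TRUE, digits = NA)
      summary$single_cell <- list(
        genotypes = c(g1, g2),
        branch_points = c(cmp$branchPointsA, cmp$branchPointsB),
        n_specific_clusters = c(length(cmp$specificA),
                                length(cmp$specificB)))
    }
  }

  jsonlite::write_json(summary, o("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(summary)
}
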