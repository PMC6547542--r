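# Directional group conventions shared by the simulator and the grouping
# stage.  Axis A is the first mutant, axis B the second:
#   1 both up; 2 A up only; 3 B up only; 4 A up / B down;
#   5 A down / B up; 6 B down only; 7 A down only; 8 both down.
.GROUP_DIR <- data.frame(
  group = as.character(1:8),
  dirA = c(1, 1, 0, 1, -1, 0, -1, -1),
  dirB = c(1, 0, 1, -1, 1, -1, 0, -1))

#' Simulate the bulk expression series
#'
#' Generates log-normal expression for every annotated gene over all
#' (stage, genotype, replicate) combinations.  Each gene draws one of four
#' stage-profile shapes (rising, falling, transient, flat — the planted
#' expression-pattern clusters) and one directional group from
#' `groupProportions`; grouped genes are shifted by `expressionFold` in the
#' indicated direction(s) in the corresponding mutant genotype(s), at every
#' stage.  Replicate noise is gaussian on the log2 scale with SD
#' `expressionNoiseSd` (zero gives exactly planted folds).
#'
#' @param annotation TSS annotation from [generateAnnotation()]; gene ids
#'   are taken from it.
#' @param config a [SimulationConfig()]; requires `exprReplicates >= 2`
#'   (downstream grouping averages replicates).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay `expr`
#'   (linear scale), `colData` columns `stage`, `genotype`, `replicate`
#'   (column names `stage_genotype_repN`), and truth in `rowData`: `group`
#'   (`"1" ... "8"` or `"unchanged"`, applying at every stage) and `cluster`
#'   (planted profile shape).
#' @export
simulateExpression <- function(annotation, config) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@exprReplicates < 2L)
    stop("at least 2 replicates are required (grouping averages replicates)")
  genes <- names(annotation)
  S <- length(config@stages)
  .withSeed(.childSeed(config@seed, "expression"), {
    n <- length(genes)
    sIdx <- seq_len(S) - 1L
    profiles <- rbind(
      rising = 3 * sIdx / max(1, S - 1),
      falling = rev(3 * sIdx / max(1, S - 1)),
      transient = 3 * sin(pi * sIdx / max(1, S - 1)),
      flat = rep(1.5, S))
    cluster <- sample(nrow(profiles), n, replace = TRUE)
    group <- sample(c(as.character(1:8), "unchanged"), n, replace = TRUE,
                    prob = config@groupProportions)
    dirA <- .GROUP_DIR$dirA[match(group, .GROUP_DIR$group)]
    dirB <- .GROUP_DIR$dirB[match(group, .GROUP_DIR$group)]
    dirA[is.na(dirA)] <- 0; dirB[is.na(dirB)] <- 0
    baseOffset <- rnorm(n, 0, 0.5)
    lf <- log2(config@expressionFold)
    mutA <- config@genotypes[2L]
    mutB <- if (length(config@genotypes) >= 3L) config@genotypes[3L] else NA

    cols <- list(); cd <- list()
    for (st in seq_len(S)) {
      for (gt in config@genotypes) {
        shift <- rep(0, n)
        if (gt == mutA) shift <- dirA * lf
        if (!is.na(mutB) && gt == mutB) shift <- dirB * lf
        mu <- 5 + baseOffset + profiles[cluster, st] + shift
        for (r in seq_len(config@exprReplicates)) {
          nm <- paste(config@stages[st], gt, paste0("rep", r), sep = "_")
          noise <- if (config@expressionNoiseSd > 0)
            rnorm(n, 0, config@expressionNoiseSd) else 0
          cols[[nm]] <- 2^(mu + noise)
          cd[[nm]] <- c(config@stages[st], gt, r)
        }
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- genes
    se <- SummarizedExperiment(
      assays = list(expr = m),
      colData = DataFrame(stage = unname(vapply(cd, `[`, "", 1L)),
                          genotype = unname(vapply(cd, `[`, "", 2L)),
                          replicate = as.integer(vapply(cd, `[`, "", 3L)),
                          row.names = names(cols)),
      rowData = DataFrame(group = group,
                          cluster = rownames(profiles)[cluster],
                          row.names = genes))
    se
  })
}
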