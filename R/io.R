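# Tabular readers/writers for the pipeline's text formats.  All tables are
# tab-separated with a header row; the first column is the row id.

#' Write / read a tag-count table as TSV
#'
#' First column `peak_id`, one column per sample.  Sample names of the form
#' `factor_genotype_repN` are parsed back into `colData` on reading.
#'
#' @param table a [TagCountTable()].
#' @param path file path.
#' @return `path` invisibly (write); a raw `TagCountTable` (read).
#' @export
writeTagCounts <- function(table, path) {
  stopifnot(is(table, "TagCountTable"))
  df <- data.frame(peak_id = rownames(table), assay(table, "counts"),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTagCounts
#' @export
readTagCounts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  parts <- strsplit(colnames(m), "_")
  cd <- if (all(lengths(parts) == 3L))
    DataFrame(factor = vapply(parts, `[`, "", 1L),
              genotype = vapply(parts, `[`, "", 2L),
              replicate = as.integer(sub("rep", "",
                                         vapply(parts, `[`, "", 3L))),
              row.names = colnames(m))
  else DataFrame(row.names = colnames(m))
  TagCountTable(m, colData = cd)
}

#' Write / read an expression matrix as TSV
#'
#' First column `gene_id`; column headers encode
#' `stage_genotype_repN`.
#'
#' @param expr a `SummarizedExperiment` with an `expr` assay.
#' @param path file path.
#' @return `path` invisibly (write); a `SummarizedExperiment` (read).
#' @export
writeExpressionTable <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), assay(expr, 1),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTable
#' @export
readExpressionTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  parts <- strsplit(colnames(m), "_")
  if (any(lengths(parts) != 3L))
    stop("expression column names must encode stage_genotype_repN")
  SummarizedExperiment(
    assays = list(expr = m),
    colData = DataFrame(stage = vapply(parts, `[`, "", 1L),
                        genotype = vapply(parts, `[`, "", 2L),
                        replicate = as.integer(sub("rep", "",
                                                   vapply(parts, `[`, "", 3L))),
                        row.names = colnames(m)))
}

#' Write / read a single-cell matrix as TSV plus metadata
#'
#' The counts file has genes as rows (first column `gene_id`) and cells as
#' columns; the metadata file has one row per cell.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param countsPath,metaPath file paths.
#' @return `countsPath` invisibly (write); a `SingleCellExperiment` (read).
#' @export
writeCellMatrix <- function(sce, countsPath, metaPath) {
  df <- data.frame(gene_id = rownames(sce), as.matrix(assay(sce, "counts")),
                   check.names = FALSE)
  write.table(df, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(cell_id = colnames(sce),
                     as.data.frame(colData(sce)), check.names = FALSE)
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(countsPath)
}

#' @rdname writeCellMatrix
#' @export
readCellMatrix <- function(countsPath, metaPath) {
  df <- read.table(countsPath, sep = "\t", header = TRUE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  meta <- read.table(metaPath, sep = "\t", header = TRUE,
                     check.names = FALSE)
  rownames(meta) <- meta$cell_id
  SingleCellExperiment(assays = list(counts = m),
                       colData = DataFrame(meta[colnames(m),
                                                -1L, drop = FALSE]))
}

#' Write / read a TSS annotation as TSV
#'
#' Columns `gene_id`, `chrom`, `pos` (0-based TSS position), `strand`.
#'
#' @param tss annotation from [tssAnnotation()].
#' @param path file path.
#' @return `path` invisibly (write); a TSS `GRanges` (read).
#' @export
writeTss <- function(tss, path) {
  df <- data.frame(gene_id = if (length(tss)) names(tss) else character(),
                   chrom = as.character(seqnames(tss)),
                   pos = start(tss) - 1L,
                   strand = as.character(strand(tss)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTss
#' @export
readTss <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  tssAnnotation(df$gene_id, df$chrom, df$pos, df$strand)
}
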