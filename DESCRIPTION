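Package: chromDuet
Title: Comparative Two-Factor Chromatin Occupancy and Differentiation
    Trajectory Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the genome-wide occupancy of two related
    transcription factors from ChIP-seq tag counts over a shared,
    ATAC-filtered peak universe, and for following the downstream
    consequences of losing one factor through bulk and single-cell
    expression data. Implements shared/specific peak classification by
    fold change, detection of de novo acquired or lost binding in mutant
    genotypes, position-weight-matrix motif counting stratified by peak
    class and promoter/distal location, directional differential-expression
    grouping across two mutants, covariance clustering of expression
    profiles, and a minimum-spanning-tree pseudotime with branch-point
    counting for genotype comparison. A synthetic-data generator plants
    known peak classes, motif placements, expression groups and lineage
    topologies so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
biocViews: ChIPSeq, ATACSeq, Transcription, GeneExpression, SingleCell,
    Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
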