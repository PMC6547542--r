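---
title: "chromDuet: models, conventions and design choices"
author: "chromDuet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromDuet: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the statistical models, parameter conventions and
design decisions behind chromDuet, in the spirit of the methods sections of
the established Bioconductor analysis packages.  The package compares the
genome-wide occupancy of two related transcription factors (the motivating
system is Sp1/Sp3 cooperation during hematopoietic specification from
embryonic stem cells) and follows the consequences of disrupting one factor
through bulk and single-cell expression.

# The comparative-occupancy model

All occupancy comparisons operate on a **tag-count table**: a peaks ×
samples matrix of non-negative signal over a common peak universe, wrapped
in a `TagCountTable` (a `SummarizedExperiment` subclass that also records
its normalisation state).  The analysis conventions are:

* **Depth normalisation.** Every column is scaled to the same total
  (`normTarget`, default $10^7$ tags).  Only ratios matter downstream, so
  the constant is arbitrary; classification refuses raw tables because a
  fold change computed across libraries of different depth is a depth
  artifact.
* **Replicates** are averaged after normalisation, before any fold change
  is taken.  Averaging stabilizes per-peak fold estimates considerably at
  realistic overdispersion (see the generator section).
* **Pseudocount.** Fold changes use a pseudocount (default 1 on the
  normalized scale) so that zeros are defined; with $10^7$-scaled counts
  the pseudocount is negligible except at truly empty peaks.
* **Inclusive thresholds.** A fold change exactly equal to the threshold
  *is* a call, everywhere ("at least twofold").  The comparative
  literature is not always consistent between "at least" and "more than"
  twofold; one inclusive rule is adopted globally for internal
  consistency, and the threshold is a parameter throughout.
* **Correlation** between samples (e.g. accessibility profiles) is
  Pearson on `log2(normalized + 1)`.  The log transform keeps the
  correlation from being dominated by a handful of strong peaks; the exact
  transform is a convention, exposed in the code rather than configurable,
  because every published variant (log2+1, rlog, asinh) gives the same
  qualitative picture at these effect sizes.

Classification of a peak is then: factor-1 specific iff
$(x_1 + pc)/(x_2 + pc) \ge f$, factor-2 specific in the symmetric case,
otherwise shared ($f$ = 2 by default).  De novo acquisition/loss applies
the same rule to one factor's signal in mutant versus wild type, restricted
to the partner-specific sites.  Both labels are partitions by
construction, antisymmetric under factor swap, and invariant to joint
rescaling — properties asserted in the test suite rather than merely
documented.

# Intervals and annotation

Peak sets are named `GRanges`; the usual Bioconductor 1-based closed
convention is used internally, and BED input/output performs the single
exact conversion to the file format's 0-based half-open coordinates, so
round-trips never shift a coordinate.

A peak is a **promoter** peak iff it overlaps the window of
`promoterWindow` bp (default ±1,000) around any TSS.  The window is placed
symmetrically regardless of gene strand: at this width the asymmetry of
real promoters is far below the peak width, and a symmetric window makes
the oracle check (an exhaustive per-TSS scan) unambiguous.  The same
distance (configurable) defines peak-to-gene **target** assignment; a peak
may serve several genes, and "target gene" has no further model behind it
— it is deliberately the simplest proximity rule.

High-confidence filtering keeps the ChIP peaks overlapping at least one
accessible (ATAC) region by at least `minOverlap` bp (default 1 bp,
matching the loose "overlapping" criterion that such filters usually
state).

# Motif content

Motifs are base-probability PWMs scored as log2 odds against a background
composition.  The scan reports every window on either strand reaching the
threshold, which defaults to 80% of the matrix's maximum achievable score
— a stringent setting appropriate for the sharp, information-rich matrices
bundled for testing (`spLikePWM()`, a synthetic 9-bp GC-box model; it is a
constructed matrix, not a database entry).  Windows containing `N` are
skipped.  Per-peak multiplicity counts non-overlapping hits by greedy
left-to-right selection — a deterministic rule; at stringent thresholds
overlapping candidate windows are rare enough that the choice of rule has
no practical effect, but it must be fixed for reproducibility.

Motif-count histograms are capped at "≥ 9" by default, mirroring the
binned bar charts such analyses are usually presented as.  Enrichment
between two peak sets uses presence/absence (≥ 1 hit) in a 2×2 Fisher
exact test; the odds ratio applies the Haldane 0.5 correction only when a
cell is zero, so non-degenerate tables report the plain cross-product
ratio.  p values are Benjamini–Hochberg adjusted across motifs.

# Bulk expression

Expression lives in a `SummarizedExperiment` with columns tagged by
(stage, genotype, replicate).  The differential criterion is a pure fold
rule — at least `foldThreshold` (default 2) between wild type and either
mutant at one or more stages, on replicate means floored at `minExpr`
(default 1 expression unit, guarding folds near zero).  No dispersion
model or significance test is layered on top: the package implements the
fold-rule analysis it sets out to implement, and the floor plus replicate
averaging are what make it stable.

"Covariance analysis" of the differential genes is agglomerative
hierarchical clustering of row Z-scores (population SD, constant rows
mapped to zero) with correlation distance and average linkage, cut at `K`
(default 13).  Correlation distance groups genes by profile *shape*, which
is what a covariance criterion targets; average linkage avoids the
chaining of single linkage and the scale sensitivity of Ward on
correlation distances.  `K` is a display-resolution choice, not an
inference — no cut-selection criterion is implied, and the per-cluster
mean profiles are exported so the user can judge the cut.

The **8-way directional grouping** at one stage maps each at-least-twofold
changed gene by its direction pair over the two mutants (A = first mutant,
B = second):

| group | A | B | | group | A | B |
|---|---|---|---|---|---|---|
| 1 | up | up | | 5 | down | up |
| 2 | up | — | | 6 | — | down |
| 3 | — | up | | 7 | down | — |
| 4 | up | down | | 8 | down | down |

The anchored positions are that shared responses sit at the ends (1 both
up, 8 both down) and the completely reciprocal responses in the middle
(4/5); the placement of the single-mutant groups between them is a
documented convention.  Swapping the mutants maps 1↔1, 8↔8, 4↔5, 2↔3,
6↔7 — asserted as a property test.

# Single cells

Preprocessing removes cells under the count/gene thresholds, scales every
cell to the median total and stores `log2(1 + x)`.  All decisions —
clustering, tree building, pseudotime — run in PCA space (top `d`
components, default 10); any nonlinear embedding is for display only, so
every downstream number is deterministic and oracle-checkable.

Clustering is k-means with a deterministic farthest-point initialization
(first centre: the cell farthest from the grand mean; then iteratively the
cell farthest from the chosen centres), followed by Lloyd iterations.
This removes the usual seed sensitivity and makes the partition invariant
to cell order, up to label permutation.

Pseudotime is the package's own transparent construction rather than a
reimplementation of any published trajectory tool: the minimum spanning
tree over cluster centroids, each cell projected to its nearest tree edge,
pseudotime measured along the tree from the root centroid, and **branch
points** counted as tree nodes of degree ≥ 3.  The root cluster must be
named by the user (for real data: the earliest-progenitor cluster);
`runPipeline()` additionally accepts synthetic datasets' recorded latent
time to pick the root, but performs no root inference on real data.
Marker genes are ranked per cluster by log2 fold change (cluster versus
rest, pseudocount 1) with a two-sided Wilcoxon rank-sum p value and BH
adjustment; clusters under 3 cells are skipped with a warning.

Genotype comparison matches clusters across genotypes by Pearson
correlation of mean log-expression profiles (greedy one-to-one matching,
cutoff 0.9).  Clusters with no counterpart above the cutoff are reported
as genotype-specific — the analogue of finding an additional lineage
cluster in a mutant — and per-gene differential expression is computed
within each matched pair.

# The synthetic-data generator

The generator is first-class, tested code.  It emulates the *structure* of
a two-factor occupancy compendium — not its raw reads: a genome of
`nChroms` × `chromLength` bp with TSSs on a jittered grid (so promoter
windows never overlap and capacity violations are detected, not silently
absorbed); a landscape of non-overlapping peaks split half promoter / half
distal within each class; negative-binomial tag counts
(`var = mu + dispersion * mu^2`, Poisson at dispersion 0); log-normal bulk
expression with four stage-profile shapes and per-group genotype offsets;
and single-cell counts along a linear, bifurcating or multifurcating
lineage with exclusive per-cluster markers, a latent-time gradient gene
block, branch-specific ramps, and (optionally) one mutant-only
off-trajectory cluster with its own marker program.

Reference conditions (the defaults) were fixed once, at design time:

* **2,000 peaks** — 1,000 shared, 400 specific to each factor, 200
  background.  The specific classes are deliberately *balanced*: with
  unequal specific counts, total-count normalisation shifts the two
  factors' scale factors apart and the realized specific-site ratio falls
  below the planted `effectFold`, violating the generator's own contract
  that empirical ratios converge to the planted fold.
* **`effectFold` 4, `dispersion` 0.1, `meanDepth` 100,
  `nReplicates` 3.**  At NB dispersion 0.1 the per-replicate log fold
  change of a single peak has SD ≈ 0.47; averaging three replicates brings
  the twofold decision margin at a planted fourfold effect to ≈ 2.5 SD,
  so fold-rule recovery is high but not trivially perfect — the regime the
  method is meant for.
* **Binding-null genotypes** draw factor-1 counts from the background
  distribution, not zero: ChIP input noise never is.
* **Expression**: five stages (ESC, Flk1, HE1, HE2, Prog), three
  genotypes, three replicates, planted fold 4, log2 replicate noise
  SD 0.1; group proportions 8 × 5% + 60% unchanged.
* **Cells**: 300 per genotype, 200 genes, bifurcating topology, Poisson
  counts with log2 jitter SD 0.3, 15% of mutant cells in the extra
  cluster.  Marker strength (3 on log2) and the gradient block (50 genes,
  slopes 2–4) were chosen together so that clusters are separable by
  k-means while the latent-time gradient still dominates the geometry —
  the regime in which a centroid-tree pseudotime is meaningful.

Determinism: every generator derives a child seed from the master seed by
a fixed hash of its stream name, so any module can be regenerated
independently; the caller's RNG state is saved and restored.

What the generator does **not** emulate — and hence what green tests do
not show about real data: read-level artifacts (GC bias, duplicates,
mappability), peak-calling uncertainty, fragment-length effects,
cross-peak signal correlation, doublets and ambient RNA in the single-cell
matrices, batch effects, and biological coupling between the occupancy and
expression layers (peak truth and gene truth are planted independently).
Recovery rates on synthetic data certify the *implementations*, not
real-data performance.

# Numerical choices and degenerate inputs

* Ties in ranking and in marker ordering break lexicographically by id;
  all outputs are deterministically sorted.
* Constant rows Z-score to zero; constant profiles get correlation 0 in
  the clustering distance; zero-variance samples are an error in
  correlation (naming the sample) rather than an NaN.
* Empty annotations annotate everything distal; empty peak sets filter to
  empty; a single cluster yields a trajectory with zero branch points and
  centroid-distance pseudotime.
* Capacity violations (genes that cannot be placed, peaks that do not fit,
  motifs longer than peaks) are errors, never silent truncation — with one
  documented exception: the per-peak motif *count* drawn from the Poisson
  multiplicity distribution is truncated to what fits non-overlapping in
  the peak, since the draw is unbounded by construction.

# Problem sizes

The test suite and the acceptance script run the reference landscape at
2,000 peaks / 1,200 genes and the single-cell stages at 300 cells per
genotype, with smaller configurations (≈ 140 peaks, 120 cells) for
integration and round-trip tests.  These sizes were chosen so that planted
effects are measured with comfortable statistical margins while the whole
suite stays interactive (well under a minute for the unit tests).

# Known limitations

* The fold-rule analyses carry no error model; they reproduce the class of
  threshold analyses they implement, and inherit their sensitivity to the
  threshold and pseudocount at shallow depth.
* The pseudotime is a centroid-level construction: it cannot resolve
  branching *within* a cluster, and its branch-point count depends on the
  clustering resolution `k`.
* Cluster matching across genotypes by profile correlation assumes mostly
  conserved expression programs; a genotype that globally rewires
  expression would defeat the 0.9 cutoff.
* `readPWM()` supports the package's tabular format and JASPAR-style count
  matrices only.
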