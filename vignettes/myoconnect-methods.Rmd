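---
title: "MyoConnect methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MyoConnect methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind MyoConnect, the
parameters that matter, the decisions taken where the methods left room,
and what the synthetic-data tests do and do not establish about real data.

# Change-heat motion quantification

## Model

A brightfield video of a contracting organoid is an intensity field
`I(t, x, y)` on [0, 1]. Periodic radial contraction moves the bright
organoid boundary back and forth over a band of pixels, so pixels in that
band show large intensity changes between frames a fixed lag apart while
static background pixels show only camera noise. The change heat

```
heat(x, y) = 1/(T - L) * sum_t | I(t + L, x, y) - I(t, x, y) |
```

averages the absolute lagged difference over all valid frame pairs; its
spatial mean is the scalar contraction score of the video. The statistic
assumes nothing about organoid shape or position — it is a pure motion
energy measure — but it does assume stable illumination: a global intensity
drift is indistinguishable from motion.

## Parameters

* `lag` (frames, default 4): the differencing interval. Short lags measure
  fast motion; the default matches the convention of differencing "every 4
  frames". It is exposed everywhere.
* Pairing (`method`): `"sliding"` uses all `T - L` pairs `(t, t + L)`;
  `"disjoint"` steps by `L` and uses non-overlapping pairs only. Sliding is
  the default because it uses all frames of the video and the disjoint
  variant is a strict subsample of its pairs; both are implemented because
  the convention is genuinely ambiguous.
* Magnitude: absolute differences by default ("gray changes" are a
  magnitude); squared differences are available behind `squared = TRUE` for
  sensitivity analyses.
* Score region: the unweighted mean over the whole frame by default, with
  an optional boolean mask. No region of interest is imposed because none
  is canonical; whole-frame means are the least arbitrary reduction, at the
  cost of diluting the score by the static background area.
* Intensities are normalized to [0, 1] on read (8-bit / 255, 16-bit /
  65535) so scores are comparable across bit depths. No background or noise
  subtraction is applied by default.

Useful exact properties, all asserted in the test suite: heat is bounded by
the intensity range; scaling all intensities by `a` scales heat and score
by exactly `a`; reversing frame order changes nothing; a static noise-free
video scores exactly 0; and the vectorized implementation equals a naive
double loop bit for bit.

Group comparison uses the classic one-way ANOVA F test on per-video scores
with conventional significance stars; groups need at least two videos each.

# The synthetic video generator

Videos are rendered as a centered disc of radius
`baseRadius * (1 + amplitude * sin(2*pi*t/period))` at foreground intensity
on a darker background. Numerical choices:

* The phase is evaluated with `sinpi()`, so the radius is *exactly*
  periodic in floating point and frame 0 equals frame `period` bit for bit
  when noise is off.
* The disc edge is anti-aliased with a one-pixel linear coverage ramp, so
  sub-pixel radius changes move pixel values smoothly and the contraction
  score responds monotonically to amplitude.
* Gaussian pixel noise is added after rendering and clipped to [0, 1],
  mimicking sensor saturation rather than wrap-around.

Default conditions (60 frames of 128 x 128 px, base radius 40 px, period
20 frames, noise sd 0.01, foreground 0.8 / background 0.2) describe a
well-exposed 40x brightfield recording of a single organoid filling about a
third of the field. What the generator does not emulate: illumination
drift, focus changes, organoid translation, or multiple organoids per
field. Tests passing on these videos show the statistic is implemented
correctly and responds to radial motion; they do not certify robustness to
those nuisances.

# Single-cell pipeline

## QC and normalization

Stage order is gene filter, then cell filter, then normalization, with cell
totals computed on the filtered matrix. The gene rule is strict (`count >
1` in at least 3 cells); the cell rule requires at least `minGenes`
detected genes (default 1000, which suits genome-wide libraries; the
synthetic configuration rescales it to a quarter of the simulated expressed
panel). Computing totals after gene filtering makes the normalization
identity exact: for every cell, `sum(exp(value) - 1)` equals the scale
factor (10<sup>4</sup>) to machine precision, which the tests assert at
1e-8. Normalized values use the natural log; the implementation is checked
against an independent reference implementation of the same normalization.

## Variable genes

Dispersion (variance/mean of the back-transformed values) is z-scored
within 20 equal-frequency bins of mean expression, removing the
mean-dispersion trend that negative-binomial counts impose; genes with
`z > 1` are selected. Genes with zero mean or zero dispersion are
uninformative and excluded; a bin with constant dispersion gets `z = 0`,
so a constant matrix selects nothing. On null data ~16 % of genes exceed
`z = 1`, which the calibration test brackets loosely.

## PCA

Selected genes are scaled to mean 0, unit variance; the cells x genes
matrix is decomposed by SVD. Zero-variance genes are dropped with a
warning. Each loading vector's sign is fixed so its largest-magnitude entry
is positive, making results deterministic up to machine precision without
affecting any rotation-invariant quantity.

## Jackstraw PC selection

In each of `nReplicates` (default 100) replicates, a random
`permutedFraction` of genes (default 1 %, at least one gene) is permuted
across cells and the PCA is recomputed with the permuted genes included.
Each permuted gene is then placed as a rank quantile within that
replicate's full absolute-loading distribution for every tested PC.

The aggregation was the one genuinely open design point. The obvious
construction — pool the permuted genes' loadings across replicates as a
null and compare the observed loadings to it — is badly miscalibrated at
small significance thresholds, for a structural reason: all observed
loadings of one PC share a single realization of the component (its
concentration across genes and its singular value), so per-gene empirical
p-values are marginally fine but massively dependent, and any
independence-based aggregate over genes (binomial, rank-sum) is
overdispersed by orders of magnitude. Within-replicate ranks remove this
common mode exactly: under the null a permuted gene is exchangeable with
every other gene *in its own replicate's decomposition*, so its quantile is
uniform regardless of how concentrated that realization happens to be. The
per-PC p-value is a one-sided exact binomial test of whether permuted-gene
quantiles land at or below `propThreshold` (default 0.1, the bottom decile)
more often than chance; a PC carrying real covariation pushes its
(signal-destroyed) permuted genes to the bottom of the loading
distribution. The suite verifies calibration on pure-noise matrices at the
working threshold of 6.02e-5 and recovery of a planted factor five times
stronger than noise; the threshold itself is kept as a plain configurable
constant.

`alpha >= 1` is treated as a vacuous threshold and returns all tested PCs
(an exact-test p-value can equal 1, so a literal `p < 1` comparison would
not).

## Clustering and markers

Cells are clustered on the significant PCs via a shared-nearest-neighbor
graph: k = 20 neighborhoods (including the cell itself), Jaccard edge
weights, edges below 1/15 pruned, Louvain community detection at
resolution 0.8. These are conventional defaults, all exposed in the
configuration; the run is seeded and clusters are relabeled by decreasing
size from 0. Recovery tests require exact agreement on well-separated
Gaussian blobs and near-exact agreement (adjusted Rand index at least 0.9)
on the negative-binomial simulation.

Markers are one-vs-rest: genes whose mean log expression differs by at
least 0.25 natural-log units in either direction are tested with the
Wilcoxon rank-sum test and Benjamini–Hochberg adjusted across the whole
table. The logFC prefilter is the standard efficiency/contract device: no
emitted row can violate the threshold. Clusters with fewer than two cells
are skipped with a warning.

# Connectivity screen

Presence of a gene in a cluster demands both a detection fraction of at
least 0.1 and mean log expression of at least 0.25. Either rule alone is
fragile — a few high-count cells can push a mean without reproducible
detection, and ambient detection can accumulate without meaningful
expression — so both are required; the thresholds travel with the result
object. Interaction counts between ordered cluster pairs are exhaustive
over the pair database; database pairs naming genes absent from the matrix
are skipped and reported rather than failing, since curated pair lists
routinely exceed any one dataset's detected genes. A secondary per-sender
mean over receivers is provided for the heatmap's "mean interactions per
cell type" reading.

Pairings are ranked by the product of the ligand's sender-cluster mean and
the receptor's receiver-cluster mean — the simplest score monotone in both
sides — with deterministic lexicographic tie-breaks, and a top-k selector
(default 50). No permutation test of interaction specificity is attempted;
the screen is a hypothesis generator, not an inference procedure.

# The synthetic expression generator

Counts are negative binomial parameterized by mean and dispersion
(`variance = mu + mu^2 * dispersion`; dispersion 0 falls back to Poisson).
Per-gene baseline means are drawn log-normally (median `baselineMean = 5`,
log-sd 1) so that gene filtering and variable-gene selection act on a
realistic abundance spread rather than a flat panel. Default conditions —
4 clusters of 140 cells (560 cells total), 800 genes, 20 markers per
cluster at natural-log fold change 1, dispersion 0.3, a 10 % silent gene
tail — emulate a small full-transcript single-cell study of a heterogeneous
muscle-derived mixture at desk scale. Planted signaling channels place the
ligand only in its sender cluster and the receptor only in its receiver
cluster (mean `baselineMean * exp(markerLogFC)`, zero elsewhere); decoy
database pairs are drawn from the silent tail, so a correct screen must
recover every planted channel and no decoy.

What the generator does not emulate: library-size variation beyond the NB
noise, dropout beyond what the NB implies, batch effects, doublets,
ambient RNA, or correlated gene programs. Passing recovery tests therefore
demonstrates correctness of the computations under the stated model, not
robustness of the pipeline to those real-data pathologies.

# Orchestration and reproducibility

`runPipeline()` chains the stages with stage-offset seeds derived from one
global seed, writes every artifact (MatrixMarket matrices, TSV/CSV tables,
PNG renderings with JSON scale sidecars, TIFF videos) and closes with a
manifest of MD5 checksums and per-stage record counts. Reruns under one
seed reproduce identical checksums; a failing stage aborts with its name
and flags retained partial output in `manifest_partial.json`. The YAML
configuration rejects unknown keys so a typo cannot silently change a
threshold.

Problem sizes throughout the tests and the acceptance script (hundreds of
genes, hundreds of cells, 100 permutation replicates, 10-60 frame videos)
were chosen so the full suite characterizes every stage, including the
permutation tests, in well under a minute per component on one CPU.

# Known limitations

* The contraction score conflates any motion with contraction; debris
  drift or stage vibration would score. No segmentation or beat-rate
  analysis is attempted.
* The jackstraw selects PCs but cannot distinguish biological from
  technical covariation.
* The marker logFC is the difference of mean log-normalized values, which
  is attenuated relative to the fold change of the underlying means at low
  expression; the planted-recovery tests account for this by testing
  recovery, not the logFC point estimate.
* The connectivity screen treats presence as binary and scores pairings by
  expression product; it has no notion of pathway context, protein-level
  abundance, or spatial adjacency.
* t-SNE or UMAP embeddings are deliberately out of scope; any standard
  implementation can be applied to the PC embedding for visualization.
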