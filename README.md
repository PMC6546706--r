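# MyoConnect

Skeletal muscle organoids built from mixed cell populations contract, and the
cell mixture that seeds them matters: rapidly adhering, largely non-myogenic
cells (RACs) boost the myogenic output of the muscle progenitor cells (MPCs)
they are co-cultured with. Two computational questions follow. *How strongly
does an organoid contract*, given nothing but a brightfield time-lapse video?
And *which ligand–receptor channels could carry the signal* between the cell
populations seen in single-cell RNA-seq of the mixture?

MyoConnect answers both with a small, fully tested toolkit:

1. **Change-heat motion quantification.** For a grayscale video
   `I(t, x, y)` with intensities in [0, 1], the per-pixel change heat at
   frame lag `L` (default 4) is

   ```
   heat(x, y) = 1/(T - L) * Σ_{t=1..T-L} | I(t + L, x, y) − I(t, x, y) |
   ```

   Bright pixels mark strongly moving regions; the spatial mean of the map
   is a scalar contraction score per organoid, and scores are compared
   across culture groups by one-way ANOVA.

2. **Single-cell preprocessing.** Gene filter (count > 1 in ≥ 3 cells), cell
   filter (≥ 1000 detected genes, rescalable), per-cell log-normalization
   `ln(1 + 10^4 · count / total)`, dispersion-z variable-gene selection,
   PCA, jackstraw permutation selection of significant PCs (α = 6.02e-5),
   shared-nearest-neighbor Louvain clustering, and one-vs-rest Wilcoxon
   marker detection at |logFC| ≥ 0.25 with Benjamini–Hochberg adjustment.

3. **Ligand–receptor connectivity screen.** A gene is *present* in a cluster
   when detected in ≥ 10 % of its cells with mean log expression ≥ 0.25;
   for every ordered (sender, receiver) cluster pair the screen counts
   database pairs with the ligand present in the sender and the receptor in
   the receiver, and ranks all pairings by the product of ligand and
   receptor mean expression (top-50 selection).

4. **Synthetic generators with planted truth** — contracting-disc videos,
   negative-binomial count matrices with planted markers and signaling
   channels, and pair databases with decoys — so that every stage is
   testable end to end without external data.

## Worked example

Score a simulated contracting organoid video and compare culture groups:

```r
library(MyoConnect)

fs <- simulateContractionVideo(nFrames = 60, amplitude = 0.2, period = 20,
                               noiseSigma = 0.01, seed = 1,
                               sourceId = "coculture_1")
hm <- computeHeatMap(fs, lag = 4)
hm
#> HeatMap 'coculture_1': 128 x 128 px, lag 4 (sliding, 56 pairs), max heat 0.2592
contractionScore(hm, group = "MR")
#>     source_id group lag n_pairs mask_area      score
#> 1 coculture_1    MR   4      56     16384 0.06306663
```

The score is the frame-wide mean change heat: 0.063 intensity units of
average absolute change per pixel per lag-4 frame pair. Three simulated
groups (strong / medium / weak contraction amplitude, three videos each)
separate cleanly:

```r
cmp <- compareGroups(scores)   # scores: per-video rows as above
cmp$groups
#>   group n   mean       sd
#> 1     M 3 0.0241 1.96e-05
#> 2    MR 3 0.0631 2.23e-05
#> 3    TM 3 0.0371 1.96e-05
cmp$anova
#>   df_between df_within       F        p stars
#> 1          2         6 2806607 1.22e-18   ***
```

Screen planted signaling channels between simulated cell clusters:

```r
ch <- data.frame(ligand = c("G0700", "G0698"), receptor = c("G0699", "G0697"),
                 sender = c(1, 3), receiver = 2)
sce <- simulateExpression(lrChannels = ch, seed = 1)
db <- simulateLRDatabase(ch[, 1:2], nDecoys = 10,
                         decoyGenes = S4Vectors::metadata(sce)$truth$silentGenes,
                         seed = 2)
sce <- logNormalize(filterCells(filterGenes(sce), minGenes = 180))
prof <- buildClusterProfile(sce)
imap <- countInteractions(callPresence(prof), db)
interactionCounts(imap)
#>   1 2 3 4
#> 1 0 1 0 0
#> 2 0 0 0 0
#> 3 0 1 0 0
#> 4 0 0 0 0
head(topPairings(scorePairings(prof, db), 3))
#>   ligand receptor sender receiver ligand_mean receptor_mean    score
#> 1  G0700    G0699      1        2    2.968930      2.979613 8.846263
#> 2  G0698    G0697      3        2    2.913801      2.925394 8.524016
#> 3  G0698    G0697      1        1    0.000000      0.000000 0.000000
```

Both planted channels are counted for exactly their planted
(sender → receiver) cluster pair and top the ranking; the 10 decoy pairs
contribute nothing.

`runPipeline(syntheticPipelineConfig(seed = 1))` chains every stage —
simulation, QC, normalization, variable genes, PCA, jackstraw, clustering,
markers, connectivity, contraction scoring — into one output directory with
a checksummed manifest; rerunning with the same seed reproduces identical
checksums.

## Package layout

- `R/moveheat.R` — change-heat statistic, scores, rendering, group ANOVA
- `R/scrna-qc.R`, `R/scrna-reduce.R`, `R/scrna-cluster.R` — the single-cell
  pipeline
- `R/connectivity.R` — cluster profiles, presence calls, interaction
  counting and pairing scores
- `R/synthetic.R` — ground-truth generators
- `R/io.R`, `R/pipeline.R` — MatrixMarket/CSV/TIFF/YAML IO and the
  end-to-end orchestration
- `vignettes/myoconnect-methods.Rmd` — the methods notes: model
  assumptions, parameter choices, calibration of the jackstraw test, and
  known limitations
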