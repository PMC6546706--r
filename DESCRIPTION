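Package: MyoConnect
Title: Contraction Quantification and Ligand-Receptor Connectivity for
    Skeletal Muscle Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies contractile activity of skeletal muscle organoids
    from time-lapse brightfield videos with a lagged frame-differencing
    "change heat" statistic, and maps candidate paracrine signaling between
    cell populations from single-cell RNA-seq. Provides a single-cell
    preprocessing pipeline (gene and cell quality filters, per-cell
    log-normalization, dispersion-based variable-gene selection, PCA with
    jackstraw permutation significance, shared-nearest-neighbor graph
    clustering, and one-vs-rest marker detection), a ligand-receptor
    connectivity screen that counts and ranks putative interactions between
    ordered cluster pairs, and synthetic-data generators with known ground
    truth for videos, count matrices and pair databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    Seurat,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
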