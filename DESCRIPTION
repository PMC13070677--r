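Package: spadecon
Title: Spatially Regularized Autoencoder Deconvolution of Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-type deconvolution of sequencing-based spatial transcriptomics
    (ST) spots with a spatially regularized autoencoder. An encoder maps spot
    expression profiles to a nonnegative latent code with one dimension per cell
    type; a bias-free linear decoder reconstructs expression, so its weight
    matrix is directly interpretable as a cell-type-by-gene signature. Training
    is two-stage: supervised pretraining on pseudo-spots simulated from a
    labeled single-cell reference (known ground-truth proportions), then
    reconstruction-only adaptation to real ST data, both under an L1
    reconstruction loss plus a graph-Laplacian penalty built from a k-nearest
    neighbour spot graph that keeps latent codes smooth over space. Includes a
    ground-truth pseudo-spot simulator, readers and writers for MatrixMarket and
    CSV layouts, and the full evaluation-metric suite for proportion matrices
    (per-type Pearson correlation, SSIM on rasterized proportion fields,
    Jensen-Shannon divergence, RMSE, Frobenius distance) and spatial patterns
    (Moran's I, Geary's C, adjusted Rand index, cluster purity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    ape,
    Seurat,
    withr
Config/testthat/edition: 3
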