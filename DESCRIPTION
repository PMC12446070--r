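Package: histex
Title: Single-Cell Spatial Gene Expression Prediction from H&E Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multitask deep-learning framework that predicts spatially
    resolved single-cell (or spot-level) gene expression directly from
    H&E-stained histology patches. A UNet3+-style backbone performs joint
    nuclei segmentation and per-pixel cell-type classification; per-nucleus
    morphology embeddings feed auxiliary cell-type and neighborhood-composition
    heads and a reference-profile expression regressor with multi-head
    cross-attention. Includes Macenko stain normalization, transcript and cell
    quality filtering, cross-modality nucleus matching, tiling and
    cross-validation utilities, a synthetic histology generator with fully
    known ground truth, training with AdamW, whole-image inference with
    checkpoint ensembling and composition-guided cell-type recovery, and
    evaluation metrics (per-gene Pearson correlation, SSIM, stratified
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
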