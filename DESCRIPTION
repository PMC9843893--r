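Package: pancrad
Title: Pancreatic Cancer Detection on Contrast-Enhanced CT with 2D and 3D Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end computer-aided detection pipeline for pancreatic
    cancer on contrast-enhanced CT. Reads CT volumes and pancreas/tumor label
    masks, resamples them onto a canonical 1x1x5 mm grid, extracts first-order
    and gray-level texture radiomic features (GLCM, GLRLM, GLSZM, GLDM, NGTDM)
    on original, wavelet- and Laplacian-of-Gaussian-filtered images, trains
    gradient-boosted tree classifiers at the whole-pancreas (3D) and
    20x20-pixel patch (2D) level, aggregates patch probabilities into per-slice
    heatmaps with a largest high-risk-region area statistic, fuses the two
    branches with a logistic model, and reports diagnostic accuracy with exact
    binomial confidence intervals, likelihood ratios, DeLong AUC comparisons
    and size-stratified sensitivity. A seeded phantom generator produces
    synthetic pancreas-like cohorts so the whole pipeline is trainable and
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    xgboost,
    jsonlite,
    glmnet,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
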