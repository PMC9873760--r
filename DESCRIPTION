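Package: lfsvalue
Title: Feature-Based Construction of Aesthetic Value: Image Features,
    Linear Feature Summation Modeling, and fMRI Encoding Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how subjective aesthetic value is constructed
    from stimulus features. Computes an interpretable bank of low-level visual
    features from raster images (segmentation-based color, shape and entropy
    statistics, blur, symmetry), fits the linear feature summation (LFS) value
    model to liking ratings with cross-validated ridge regression and
    permutation nulls, selects a shared feature set across participants by
    sparse PCA and group-lasso (FISTA), builds nonlinear interaction features,
    and tests hierarchical feature encoding, feature-value integration (PPI
    overlap) and layerwise feature decodability on synthetic stimuli and
    simulated multi-region BOLD data. Includes a full synthetic-data generator
    (procedural images, annotations, ratings, event designs, multi-ROI BOLD)
    and a small configurable convolutional rating network with layer probes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    glmnet,
    jsonlite,
    png,
    jpeg,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
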