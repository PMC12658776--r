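Package: strokedfc
Title: Seed-Based Dynamic Functional Connectivity States and 3D-CNN
    Severity Classification for Stroke rs-fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable implementation of a
    seed-based sliding-window dynamic functional connectivity (dFC) analysis
    of resting-state fMRI in chronic stroke: cohort simulation with hidden
    connectivity states, nuisance regression and band-pass preprocessing,
    Fisher-z seed connectivity map series, L1 k-means connectivity-state
    clustering with exemplar initialization and participation-rate model
    selection, a width-scalable VGG-style 3D convolutional network trained
    under stratified 10-fold cross-validation to classify upper-limb motor
    impairment severity, and the accompanying permutation, voxelwise and
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
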