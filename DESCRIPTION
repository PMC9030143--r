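Package: LongFC
Title: Longitudinal Functional-Connectivity Classification for Alzheimer's
    Disease with Residual 1D-CNN and LSTM Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs resting-state fMRI functional-connectivity (FC)
    matrices from ROI time series (Pearson correlation over atlas-averaged
    signals, with framewise-displacement quality control), simulates
    synthetic longitudinal cohorts with group- and timepoint-specific
    connectivity structure, augments per-class training sets with a
    generative adversarial network over vectorized FC edges, and classifies
    three-timepoint FC sequences (baseline, 12 months, 24 months) with a
    weight-shared residual one-dimensional convolutional feature extractor
    fused by a three-layer LSTM. Includes a stratified five-fold
    cross-validation harness with confusion-matrix metrics, ROC/AUC, and
    SVM and CNN-only baselines, plus an end-to-end reproducible pipeline
    driver and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
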