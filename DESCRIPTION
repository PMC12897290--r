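Package: fmricv
Title: Leakage-Controlled Task-fMRI Classification of Patient Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates emotional Go/NoGo task BOLD cohorts with known
    ground-truth group effects and runs a leakage-controlled analysis
    pipeline on them: framewise-displacement motion QC and scrubbing,
    Friston-24 nuisance regression, band-pass filtering and Gaussian
    smoothing, first- and second-level GLM contrast z-maps, Gaussian
    random field cluster correction, fold-internal abnormal-ROI
    time-series feature construction, nested stratified cross-validated
    classification with bootstrap confidence intervals, Shapley-value
    ROI importance, and GRF-corrected brain-behavior regression with
    Benjamini-Hochberg FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    glmnet,
    e1071,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
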