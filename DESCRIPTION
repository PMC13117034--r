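Package: attnmil
Title: Dual-Attention Adaptive Bag-Embedding Multiple-Instance Learning for 3D Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Weakly-supervised classification of 3D medical volumes with
    multiple-instance learning (MIL). A patient's volume is a bag of
    slice-level instances; a compact 3D convolutional backbone extracts
    per-instance deep features, a first attention layer scores instances,
    and a second layer selects an adaptively-sized set of critical
    instances and builds a calibrated bag embedding from inner-product
    softmax distances. The package also provides the surrounding
    multimodal pipeline: univariate screening and coordinate-descent
    LASSO selection for clinical/dosimetric and radiomics-style feature
    tables, concatenation fusion with a sigmoid multilayer perceptron
    predictor, stratified patient-level splitting with 5-fold
    cross-validation, bootstrap AUC confidence intervals, an ablation
    harness, and a seeded synthetic cohort generator with planted key
    slices for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
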