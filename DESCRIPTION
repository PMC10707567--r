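Package: maacnn
Title: Multi-Atlas Attention Convolutional Networks for Functional
    Connectivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classify subjects from resting-state fMRI functional
    connectivity using a multi-view (multi-atlas) deep model: per-atlas
    stacked denoising autoencoders compress lower-triangle Pearson
    correlation features to a common width, an attention block learns
    per-subject view weights from global-average-pooled summaries and
    fuses the views by a convex combination, and a one-dimensional
    convolutional network with batch normalization, max pooling, dropout,
    L2 weight decay and a projection skip connection produces two-class
    probabilities. Includes readers for ABIDE-style ROI time-series files,
    stratified k-fold and leave-one-out cross-validation with
    leakage-safe in-fold fitting, recursive feature elimination and
    ablation harnesses, evaluation metrics (accuracy, sensitivity,
    specificity, AUC), and a synthetic multi-atlas cohort generator with
    planted covariance effects so the full pipeline is testable without
    real imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
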