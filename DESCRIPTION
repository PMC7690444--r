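Package: pmfesn
Title: Parallel Multi-Parametric Feature-Embedded Siamese Networks for
    Ordinal Stroke Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Few-shot similarity learning for predicting the three-month
    modified Rankin Scale (mRS 0-4) of acute ischemic stroke patients from
    six co-registered MRI parameter maps (ADC, MTT, TTP, Tmax, CBV, CBF).
    Implements a parallel multi-parametric feature-embedded siamese network
    with a two-stage class-balancing strategy (geometric augmentation to
    equalize class counts, then balanced same/dissimilar pair construction),
    a leave-one-case-out evaluation harness, and an imbalance-insensitive
    metric suite (macro-averaged MAE, macro precision/recall/F1, multiclass
    Matthews correlation, per-class AUC). Includes a synthetic
    multi-parametric data generator so the full pipeline is testable without
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
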