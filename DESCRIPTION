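Package: umetab
Title: Untargeted Plasma Metabolomics Pipeline with Internal-Standard
    Normalization and Cross-Validated Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing untargeted LC-MS feature-abundance tables
    from case-control cohorts: detection-threshold feature filtering,
    internal-standard principal-component regression normalization with
    batch-effect diagnostics, oversampled and noise-regularized random-forest
    leave-one-out cross-validation with bootstrap ROC/AUC, repeated-subsample
    robustness checks, PCA/t-SNE/PLS-DA embeddings with confidence ellipses,
    and per-feature differential-abundance screening with false-discovery-rate
    control. Includes a synthetic-cohort generator reproducing the statistical
    structure of a two-batch uveal-melanoma plasma metabolomics study so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
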