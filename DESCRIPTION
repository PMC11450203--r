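Package: cloneRx
Title: Clone-Specific Drug and Dose Prediction from Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts patient- and subclone-specific effective drugs and doses
    from a single scRNA-seq count matrix. A dose-aware gradient-boosted
    regressor of percent inhibition is trained on a reference database that
    matches drug perturbation signatures to dose-response viability curves by
    log-dose interpolation, with drug structure encoded as binary circular
    fingerprints. A clone-calling pipeline derives normal/malignant labels,
    expression-based CNV profiles and two broad subclones from the count
    matrix, computes clone-versus-normal differential-expression signatures,
    and ranks confidence-filtered, dose-capped drug predictions per clone,
    assembling selective two-drug combination plans. Pharmacometric scoring
    (plate-control normalization, four-parameter logistic fitting, ZIP
    synergy on dose matrices, drug sensitivity scores, ROC/AUC with DeLong
    comparison) supports retrospective and prospective validation. A fully
    synthetic data generator emulates the perturbation/viability reference
    and clonally structured patients so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    xgboost,
    igraph,
    minpack.lm,
    pROC,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
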