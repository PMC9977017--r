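Package: physiomot
Title: Physio-Motor Biomarkers of Rett Syndrome Severity from Wearable Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deriving digital physio-motor biomarkers of Rett
    syndrome severity from gappy wearable recordings. Implements signal
    quality index (SQI) based multi-channel ECG fusion, shape-preserving
    hourly activity imputation, and stochastic surrogate gap imputation;
    windowed heart-rate-variability metrics including phase-rectified
    signal averaging (deceleration capacity); actigraphy features from
    Oakley activity counts (interdaily stability, intradaily variability,
    L5/M10, cosinor rhythmometry); multiscale transfer entropy estimated
    with Darbellay-Vajda adaptive partitioning; multiscale transition
    network representation metrics; and L1-penalised logistic severity
    classification with leave-one-patient-out cross-validation, pooled
    AUC and feature popularity scores. A synthetic cohort generator with
    closed-form coupling oracles supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    igraph,
    signal,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
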