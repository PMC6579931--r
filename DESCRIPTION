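Package: cvcreact
Title: Cardiac Vagal Control Reactivity from Interbeat-Interval Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying cardiac vagal control (CVC) across a
    baseline-stressor-recovery protocol from interbeat-interval (IBI/RR)
    recordings. Provides a seeded RR-interval simulator with respiratory and
    low-frequency modulation, vagal withdrawal during stress, and beat
    artifacts; IBI reading/writing, automated artifact detection and
    correction, and condition segmentation; moving-window estimates of RMSSD,
    log-variance heart-rate variability, band-limited respiratory sinus
    arrhythmia (0.12-0.4 Hz FIR), mean heart rate, and a respiration-rate
    validity check; a statistical battery (Spearman matrices with Bonferroni
    correction, log-transformed baseline regressions with partial
    eta-squared, stepwise subscale selection, generalized-least-squares
    repeated-measures models with unstructured within-subject correlation,
    AIC/likelihood-ratio model comparison, LASSO covariate screening); and
    responder classification by principal components and Ward hierarchical
    clustering with Mann-Whitney group tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lmtest,
    MASS,
    nlme,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
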