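Package: srmpanel
Title: Targeted-Proteomics Quantification and Prognostic Panel Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tidy pipeline from selected-reaction-monitoring (SRM)
    heavy/light peak-area ratios to a multi-protein prognostic classifier.
    Fits isotope-dilution calibration curves with signal-to-noise based
    limits of detection and quantification, back-calculates endogenous
    peptide concentrations from light-over-heavy ratios, evaluates single
    markers against binary and survival endpoints (AUC with bootstrap
    confidence intervals, constrained ROC cut-point optimisation,
    Kaplan-Meier and log-rank analysis), and trains a 0-100 scaled
    logistic panel classifier with a bootstrapped decision threshold that
    must satisfy negative-predictive-value and specificity constraints.
    Includes a synthetic-data generator reproducing the statistical
    structure such pipelines assume, so every stage is testable without
    access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    survival,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
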