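Package: raprout
Title: CSF Dynamics Simulation and RAP/Rout-Based Shunt Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cerebrospinal fluid (CSF) pressure-volume
    compensation in hydrocephalus before shunt surgery. Simulates intracranial
    pressure (ICP) recordings from a Marmarou-type CSF dynamics model under
    baseline, constant-rate infusion and continuous lumbar drainage protocols;
    derives the fundamental pulse amplitude (AMP) and the compensatory reserve
    index RAP (moving correlation of AMP and mean ICP) from raw waveforms;
    estimates the resistance to CSF outflow (Rout) from infusion tests;
    reduces 48-hour drainage recordings to segment-wise RAP maxima and their
    relative declines; and evaluates logistic outcome-prediction models with
    ROC/AUC (DeLong intervals), Youden cut-offs, diagnostic metrics and
    Hosmer-Lemeshow calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
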