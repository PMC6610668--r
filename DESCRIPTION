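Package: radntcp
Title: Age-Adjusted Normal Tissue Complication Probability Models for
    Radiation-Associated Dysphagia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dosimetric analysis of chronic radiation-associated
    dysphagia after head-and-neck radiotherapy. Parses and validates per-ROI
    dose-volume histograms, reduces them to fractionation-corrected (EQD2)
    generalized mean doses (gEUD), fits logistic normal tissue complication
    probability (NTCP) models with age and other clinical covariates by
    maximum likelihood, selects covariates by forward-stepwise BIC, attaches
    FDR-adjusted p-values and ROC AUC diagnostics, bootstraps dose-response
    curves, and inverts fitted models into age-stratified mean-dose
    constraints at a fixed predicted-risk level. Includes a synthetic cohort
    and DVH generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
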