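Package: amikelder
Title: Population Pharmacokinetics and Renal Dosing Simulation of Amikacin
    in Elderly Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonparametric adaptive-grid population pharmacokinetic
    estimation for sparse peak/trough therapeutic-drug-monitoring data of
    amikacin in elderly patients, using a one-compartment intravenous
    infusion model with creatinine-clearance covariate scaling of drug
    clearance (a two-compartment comparator is included for model
    selection).  Provides a synthetic sparse-TDM cohort generator,
    covariate model building by likelihood-ratio and AIC rules, visual
    predictive checks, bootstrap stability assessment, Monte Carlo
    probability-of-target-attainment simulation against peak-to-MIC
    efficacy and trough safety targets, fractional target attainment over
    MIC frequency distributions, and construction of a creatinine-
    clearance-based initial-dose nomogram.
License: MIT
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
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
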