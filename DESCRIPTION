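Package: prscreen
Title: Risk-Adapted Prostate Cancer Screening with Polygenic Risk Scores
    and Age-Specific PSA Cut-Offs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to build and select polygenic risk scores (PRS) from SNP
    dosage data, derive PRS-specific and age-specific prostate-specific
    antigen (PSA) screening cut-offs from time-dependent ROC curves at a
    fixed horizon with inverse-probability-of-censoring weighting, quantify
    incidence and mortality associations with proportional-hazards models,
    and evaluate risk-adapted screening positivity strategies against
    traditional fixed-threshold PSA screening. Includes a calibrated
    synthetic-cohort generator emulating a PLCO-like screening trial so the
    full pipeline can be exercised and tested without access to
    individual-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    forcats,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
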