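Package: phenosim
Title: Simulated Clinical Trials with Phenotype-Dependent Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates parallel-group randomised controlled trials in which
    treatment response is governed by a known non-linear rule over a small set
    of phenotype variables, then contrasts what a traditional inferential
    analysis (arm-level effect estimates, subgroup forest tables, number
    needed to treat) recovers with what a cross-validated gradient-boosted
    classifier recovers when predicting individual treatment response.
    Includes Shapley-value interrogation of the fitted models, and scenario
    drivers that probe robustness to a missing response-determining covariate
    (data deficiency), to thousands of added noise covariates (data excess),
    and to replicate re-simulation (power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
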