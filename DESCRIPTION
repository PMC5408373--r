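Package: psmatchdr
Title: Double-Adjustment After Propensity-Score Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo machinery for studying residual covariate imbalance
    after 1:1 propensity-score matching and its correction by regression
    double-adjustment. Generates virtual perioperative cohorts from
    configurable logistic treatment and outcome models (linear/additive and
    non-linear/non-additive scenarios), matches treated to control units by
    greedy nearest-neighbor matching on the estimated propensity score
    without replacement or caliper, quantifies residual imbalance by
    standardized mean differences (SMD), and evaluates crude and
    double-robust estimators of the average treatment effect in the treated
    (ATT) across a grid of SMD thresholds used to choose the covariates for
    adjustment, reporting relative bias, mean squared error and
    biased-estimate percentages across replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ggplot2,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
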