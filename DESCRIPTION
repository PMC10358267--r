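Package: pssval
Title: External Validation of Preoperative Survival Scoring Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating preoperative survival scoring
    systems (PSSs) used in surgical decision-making for skeletal metastasis.
    Computes fixed-horizon discrimination (c-index), Brier scores benchmarked
    against the null (prevalence) model, logistic-recalibration calibration
    intercepts and slopes, log observed:expected survivor ratios, decision
    curves (net benefit), and a model-consistency statistic that flags
    survival predictions that increase with the time horizon. Includes a
    calibrated synthetic-cohort generator reproducing the marginal mortality,
    ascertainment, covariate, and lab-missingness structure of a metastatic
    extremity surgery cohort, and an iterative random-forest (missForest-style)
    imputation routine with a complete-case sensitivity pathway.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
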