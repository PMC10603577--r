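Package: eiscreen
Title: Risk Model-Based Lung Cancer Screening Eligibility and Disparity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating lung cancer screening strategies in
    multiethnic cohorts. Implements PLCOm2012-family 6-year absolute risk
    scoring from declarative coefficient files, constrained recalibration of
    race/ethnicity parameters by offset logistic regression, rule-based
    (USPSTF 2013/2021) and risk-threshold eligibility, race-stratified model
    validation (AUC, decile calibration and slope, Brier score, cross
    validation), and the eligibility-incidence (E-I) ratio disparity analysis
    with Poisson rate-ratio inference and screening performance metrics
    (sensitivity, specificity, number needed to screen). Includes a synthetic
    multiethnic cohort generator so the full pipeline is testable without
    access to restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
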