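# eiscreen

Tools for evaluating lung cancer screening strategies — rule-based
(USPSTF 2013/2021) versus risk-model-based — in multiethnic cohorts, with
the **eligibility-incidence (E-I) ratio** as the disparity metric.

## Who this is for

Epidemiologists and biostatisticians studying whether screening
eligibility criteria serve racial and ethnic groups in proportion to
their actual lung cancer risk. Eligibility alone is an incomplete
disparity indicator: a group can have low eligibility simply because its
smoking exposure and cancer risk are low. The E-I ratio of a group under
a criterion,

```
E-I = (screening-eligible participants) / (6-year incident lung cancer cases)
```

combines both sides (incident cases need **not** be eligible), so a low
ratio flags a group that is under-screened relative to its risk. Groups
are compared against a reference by the percent difference of their
ratios and by a two-group offset Poisson rate-ratio test, Bonferroni
corrected.

## What the package provides

* **Risk scoring** — PLCOm2012-family 6-year absolute-risk models as
  declarative YAML coefficient files (`plco_model()`,
  `load_coefficients()`, `compute_risk()`), including the merged-race
  variant (`map_race3l()`). The linear predictor is
  `logit p = β0 + Σ βk·tk(xk) + γ_race` with the published
  transformations, including the nonlinear smoking-intensity term
  `(cigs/day / 10)^-1`.
* **Constrained recalibration** — `fit_race_recalibration()` re-estimates
  only the race/ethnicity parameters (an intercept shift plus per-race
  coefficients, White reference) on a target cohort by exact offset
  logistic MLE, keeping all other coefficients frozen;
  `crossfit_predictions()` is the stratified 10-fold CV harness.
* **Eligibility** — `uspstf_2021()`, `uspstf_2013()`, `risk_criterion()`,
  `is_eligible()`, and `match_threshold()` (the risk cutoff that matches
  a rule-based eligible count).
* **Validation** — `auc()` (+ stratified-bootstrap CI), decile
  `calibration()` with OLS slope, `brier()`, per-group
  `validation_report()`.
* **Disparity & performance** — `ei_ratio()`, `percent_difference()`,
  `poisson_compare()`, `disparity_table()`, `screening_performance()`,
  `performance_table()`.
* **Synthetic cohorts** — `synthetic_spec()` / `generate_cohort()` draw
  multiethnic cohorts with realistic per-race smoking marginals and
  outcomes from a known risk model tuned to a target incidence, so the
  whole pipeline is testable without restricted data.
* **Pipeline** — `run_pipeline()` chains
  simulate → score → recalibrate → validate → eligibility → disparity →
  report into one output directory with a run manifest;
  `inst/scripts/eiscreen.R` is a thin command-line wrapper.

## Worked example

The packaged counts fixture (`cohort_counts_fixture()`) holds per-group
totals, 6-year incident cases, and eligible counts under three criteria
for a five-group cohort of 105,261 ever-smokers. The disparity analysis
under the USPSTF 2021 rule:

```r
library(eiscreen)
counts <- read_group_counts(cohort_counts_fixture())
res <- disparity_table(counts)
subset(res, criterion == "uspstf_2021",
       select = c(group, eligible, incident_cases, ei_ratio_rounded,
                  percent_difference, p_value, significant))
```

```
              group eligible incident_cases ei_ratio_rounded percent_difference  p_value significant
1  african_american     4115            432              9.5             -53.20 0.00e+00        TRUE
2 japanese_american     6932            315             22.0               8.37 2.52e-07        TRUE
3            latino     3360            159             21.1               3.94 3.70e-02       FALSE
4              nhpi     2104            125             16.8             -17.24 2.37e-14        TRUE
5             white     8771            433             20.3               0.00       NA          NA
```

Reading: to detect one lung cancer case among White participants, the
2021 rule makes 20.3 people eligible; among African American
participants only 9.5 — a 53% lower E-I ratio (p < .001 after Bonferroni),
i.e. markedly less screening eligibility per case despite the group's
higher incidence. Under the risk-based criterion in the same fixture
(`criterion == "plco_update"`) the African American ratio rises to 15.9
vs 18.4 for White — the disparity narrows.

The individual-level machinery on a synthetic cohort:

```r
co <- generate_cohort(synthetic_spec(20000, seed = 42))
base <- plco_model("original")
fit <- fit_race_recalibration(co, base)
fit
```

```
<recalibration_result> plcom2012_original_update: converged in 6 iterations, logLik -1357.36
          parameter   estimate        se
1   intercept_shift  0.4587193 0.1040035
2  african_american  0.4511141 0.1559128
3 japanese_american -0.5026659 0.1756386
4            latino -1.0870024 0.2794458
5              nhpi  0.9629476 0.1744586
```

```r
sc  <- compute_risk(co, fit$updated_model)
thr <- match_threshold(sc, co$age, sum(is_eligible(co, uspstf_2021())))
sprintf("eligibility-matched 6-year risk threshold: %.4f", thr)
#> "eligibility-matched 6-year risk threshold: 0.0146"
```

The matched threshold makes risk-based eligibility the same size as the
rule-based pool, so the two strategies are compared at equal screening
volume.

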