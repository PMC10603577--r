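---
title: "Risk-based lung cancer screening eligibility and the E-I ratio: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-based lung cancer screening eligibility and the E-I ratio: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiscreen)
```

## The problem

National lung cancer screening guidelines select candidates by age and
smoking history alone (the USPSTF 2021 rule: age 50–80, at least 20
pack-years, current smoker or quit within 15 years; the stricter 2013 rule:
age 55–80, 30 pack-years). Because smoking patterns and baseline lung
cancer risk differ across racial and ethnic groups, a rule that ignores
risk can leave a high-risk group with disproportionately little screening.
`eiscreen` implements the machinery needed to quantify that problem and to
evaluate the alternative — risk-model-based eligibility — in a multiethnic
cohort:

1. a declarative evaluator for PLCOm2012-family 6-year absolute-risk
   models;
2. constrained recalibration of the race/ethnicity-related parameters on a
   target cohort;
3. rule-based and risk-threshold eligibility, including the
   eligibility-matched threshold;
4. race-stratified validation metrics (AUC, decile calibration, Brier);
5. the eligibility-incidence (E-I) ratio disparity analysis with Poisson
   rate-ratio inference, and screening performance (sensitivity,
   specificity, number needed to screen).

A synthetic cohort generator stands in for the restricted cohort data, so
every stage is exercised end to end by code alone.

## The risk model

PLCOm2012 is a logistic model for 6-year incident lung cancer among
ever-smokers. For participant $i$ with covariates $x_i$ and race $r_i$,

$$\operatorname{logit}\, p_i \;=\; \beta_0 + \sum_k \beta_k\, t_k(x_{ik}) + \gamma_{r_i},$$

where the $t_k$ are fixed transformations (centering for age, education,
BMI, smoking duration and quit-years; indicators for COPD/emphysema,
personal cancer history, family history of lung cancer and current
smoking; and the nonlinear intensity transform
$(\text{cigarettes/day}/10)^{-1}$ minus its centering constant) and
$\gamma_r$ is the race/ethnicity coefficient with White as the reference
($\gamma_{\text{white}} = 0$).

The model lives in a versioned YAML file, not in code: the packaged
`plcom2012_original.yaml` carries the published coefficients, and any
recalibrated or merged-race variant is just another file consumed by the
same evaluator (`compute_risk()`). The intensity transform is a declared
token (`reciprocal_scaled`) with its scale and centering constant as data,
because hard-coding it would make the three model variants three code
paths. Out-of-range covariates are used as-is — the evaluator never clamps
— since clamping silently changes risk for exactly the heavy-exposure
records that drive eligibility.

The merged-race ("3-level") variant maps Japanese American, Latino, and
Native Hawaiian/Other Pacific Islander to the White reference
(`map_race3l()`). The packaged `plcom2012_race3l.yaml` is constructed by
that category merge from the original file — a synthetic stand-in, labelled
as such in its header, not a re-fitted coefficient set — so merged-map
scoring is exactly original-model scoring after mapping.

## Constrained recalibration

A model developed in one population is often miscalibrated in another,
and differentially so by group. The recalibration re-estimates only the
race/ethnicity-related parameters on the target cohort, keeping every
other coefficient frozen: with the fixed offset
$o_i = \beta_0 + \sum_k \beta_k t_k(x_{ik})$ (the full linear predictor
minus the race term), it maximizes the Bernoulli likelihood of

$$\operatorname{logit}\, p_i = o_i + \delta_0 + \sum_{r \ne \text{white}} \delta_r\, \mathbf 1[r_i = r].$$

The intercept shift $\delta_0$ is included deliberately: pure race
indicators with a White reference could never improve calibration for the
White group itself, while an overall shift plus indicators can. This
parameterization is a design choice of the package; other software may
express the same update as five coefficients against an external
reference.

The optimizer is plain Newton/IRLS with step-halving on the
log-likelihood, run to a gradient max-norm of $10^{-8}$ (at most 100
iterations). The parameter space is tiny (1 + number of non-reference
groups), so the exact MLE is cheap and reproducible; no shrinkage or
regularization is applied. A race category with zero (or only) events is
flagged as separated: its records are dropped from the fit, its estimate
reported as non-finite, and the updated model keeps the base coefficient
for it rather than an infinite one. Tests back the fitter with two
independent oracles: the closed-form log odds ratio of a 2×2 table under a
constant offset, and `glm(y ~ race, offset = ..., family = binomial)`.

Out-of-sample performance uses `crossfit_predictions()`: folds are
stratified by outcome (fold sizes differ by at most one within each
outcome stratum, and fold labels cycle across strata so `folds = n` is
leave-one-out), the recalibration is fitted on the training folds, and
each record is scored exactly once by a model that never saw it. The
partition is deterministic given the seed.

## Validation metrics

* **AUC** is the rank statistic (probability that a random event outranks
  a random non-event, ties counted ½). Its confidence interval is a
  stratified bootstrap (default 2000 replicates, seeded, percentile
  interval): one method that behaves identically for a 300-person group
  and the pooled cohort, instead of mixing asymptotic formulas of varying
  quality across group sizes.
* **Calibration** partitions records into deciles of predicted risk using
  the inverse-ECDF quantile convention, realized as stable-order rank
  splitting: records are ordered by score with ties broken by record
  position, then cut into ten near-equal groups, so decile counts always
  sum to $n$. The calibration slope is the OLS slope of observed event
  proportions on mean predicted risk across the deciles: 1 is perfect,
  above 1 means the model underestimates risk. With fewer distinct scores
  than bins the split degenerates into bins sharing a score value; a
  warning is emitted.
* **Brier score** is the mean squared difference between predicted risk
  and the 0/1 outcome.

## Eligibility and the matched threshold

Rule criteria apply inclusive age bounds at both ends, a pack-years
minimum, and the quit-years condition (current smokers are exempt).
Risk criteria are inclusive at the threshold — a predicted risk exactly
equal to it qualifies — and apply the 50–80 age window, so the rule-based
and risk-based strategies are compared over the same ages. Eligibility is
assessed once, at enrollment covariate values; no aging-forward.

The eligibility-matched threshold (`match_threshold()`) makes the two
strategies the same size: it returns the `target_count`-th largest
in-window risk, so at least `target_count` records qualify, with equality
when risks are tie-free. Matching is done on counts rather than
percentages to avoid rounding ambiguity. The conventional 1.3% 6-year
threshold is carried as the default configuration value, with a
sensitivity grid of 1%, 1.51%, 1.7% and 2%.

## The E-I ratio and its inference

For group $g$ under criterion $c$, the E-I ratio is
$E_{gc} / I_g$: screening-eligible participants divided by *all* 6-year
incident cases in the group — cases need not be eligible, which is exactly
why the metric captures under-service. Ratios are reported raw and rounded
to one decimal (half away from zero). Percent differences against the
reference group, $(\text{group} - \text{ref})/\text{ref} \times 100$, are
computed **from the one-decimal-rounded ratios**: reporting conventions
round the ratios first, and recomputing from unrounded counts gives
slightly different third digits, so the rounded-first convention is the
one that reproduces published tables.

Group comparisons use a two-group Poisson model for the eligible counts
with $\log I$ as offset. For this design the MLE is closed-form: rate
ratio $(E_2/I_2)/(E_1/I_1)$, standard error of its log
$\sqrt{1/E_1 + 1/E_2}$, two-sided Wald p-value. A direct
likelihood-ratio maximization backs the Wald test in the test suite; the
two agree closely near the null (the suite checks 20% relative agreement
on small-count grids with rate ratios up to 2), and diverge, as asymptotic
tests do, for extreme contrasts where both p-values are vanishingly
small. Significance is flagged after Bonferroni correction over the four
non-reference comparisons (per-test $\alpha = 0.05/4 = 0.0125$).

Screening performance: sensitivity is the percentage of cases that are
eligible, specificity the percentage of non-cases that are ineligible,
and NNS the eligible participants per eligible case, reported raw and
rounded to the nearest integer (the raw value is retained because
$\text{NNS} \times \text{sensitivity} \times \text{cases} =
\text{eligible total}$ exactly before rounding).

## The synthetic cohort

`generate_cohort()` emulates a multiethnic cohort of adults aged 45–75
with a smoking history. Per-race marginals (race mix; age, BMI, smoking
intensity and duration means/SDs; current-smoker, sex, comorbidity-flag
and family-history proportions; the 6-level education distribution)
default to the enrollment characteristics of the five-group cohort the
package is designed around, e.g. overall intensity mean 14.8 (SD 8.3)
cigarettes/day and duration mean 22.5 (SD 12.5) years. Shapes are
implementation choices, documented here because only means and SDs are
published: truncated normals for age ([45,75]), BMI, intensity (floor 1
cigarette/day) and duration (floor 1 year, capped at age − 18);
quit-years for former smokers from an exponential with the per-race mean,
truncated at age − 18 − duration. Pack-years are derived exactly as
intensity/20 × duration. COPD/emphysema prevalence is not published for
this cohort; the default of 8% among ever-smokers is a documented guess,
and the cohort reader separately imputes missing COPD flags as `FALSE`
with a logged count — a flagged convention, not an assertion about how any
real cohort ascertained it.

Outcomes are drawn Bernoulli from a known "true" coefficient set whose
intercept is shifted (by root-finding on the mean risk) so the expected
incidence matches a target, default 1.4% over 6 years. Correlations
between covariates beyond those induced by race and by the pack-years
derivation are *not* modeled. Passing tests on these cohorts therefore
demonstrates correctness of the estimators and pipeline — parameter
recovery, calibration of the self-scored model, determinism — not that any
particular published estimate generalizes; cohort-specific quantities
like per-group AUCs or calibration slopes of a real population cannot be
reproduced from synthetic data and are not asserted anywhere.

## Numerical and degenerate-input conventions

* Risk is `plogis(lp)`; the logit/logistic identity is exact to machine
  precision on the log scale and on the sub-50% risk scale where 6-year
  risks live.
* The intensity transform is undefined at 0 cigarettes/day; scoring such
  a record is a fatal error rather than a silent clamp (the study
  population is ever-smokers, so a zero is a data error).
* E-I ratio with zero incident cases is undefined and raises an error;
  zero eligible counts in the Poisson comparison get a 0.5 continuity
  adjustment with a warning.
* `match_threshold(target = 0)` returns `Inf`, the "none eligible"
  sentinel.
* All randomness (cohort generation, fold partition, bootstrap) flows
  from explicit seeds; the pipeline expands one root seed per stage, and
  rerunning with the same configuration reproduces every stage output
  byte-identically (the run manifest's wall-clock timestamp aside).

## Problem sizes

The test suite exercises parameter recovery at $n = 100\,000$ (the scale
at which the ±0.15 recovery tolerance for injected race offsets of +0.5
and −0.4 is comfortably within the binomial information at 1.4%
prevalence), calibration self-consistency at $n = 50\,000$, and the full
pipeline smoke/determinism checks at $n = 2\,000$–$3\,000$ with a reduced
bootstrap (50 replicates), sizes chosen to keep the default suite fast
while leaving the statistical assertions well-powered.

## Known limitations

* The packaged coefficient file is a transcription; the package does not
  bundle the other leading risk models (LCRAT, Bach, LLPv3), though the
  `coefficient_set` interface admits them.
* The merged-race variant file is derived by category merging, not
  re-fitted.
* The Poisson comparison is the two-group offset model; no covariate
  adjustment.
* The synthetic generator does not emulate geographic sampling, calendar
  time, competing mortality, or covariate correlations beyond race.
* Outcomes are a fixed 6-year binary window; there is no censoring or
  survival structure.
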