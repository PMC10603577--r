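test_that("two-race fit recovers the 2x2 log odds ratio exactly", {
  co <- two_race_cohort(n_w = 100, ev_w = 10, n_a = 100, ev_a = 30)
  base <- toy_model(intercept = -2,
                    races = c(white = 0, african_american = 0.1,
                              japanese_american = -0.1, latino = 0.2,
                              nhpi = 0.3))
  fit <- fit_race_recalibration(co, base)
  expect_true(fit$converged)
  # with a constant offset the 2-parameter fit saturates the 2x2 table:
  # delta_aa = log((30/70) / (10/90)), delta0 = logit(0.1) - offset
  est <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  expect_equal(unname(est["african_american"]),
               log((30 / 70) / (10 / 90)), tolerance = 1e-8)
  expect_equal(unname(est["intercept_shift"]), qlogis(0.1) - (-2),
               tolerance = 1e-8)
  # updated model differs from the base only in intercept and race map
  expect_equal(fit$updated_model$terms, base$terms)
  expect_equal(fit$updated_model$intercept,
               base$intercept + est[["intercept_shift"]])
})

test_that("estimates agree with an off-the-shelf offset logistic fit", {
  set.seed(42)
  co <- generate_cohort(synthetic_spec(8000, seed = 42,
                                       target_incidence = 0.05))
  base <- quiet_plco("original")
  fit <- fit_race_recalibration(co, base)
  expect_true(fit$converged)

  off <- linear_predictor(co, base, include_race = FALSE)
  race <- factor(co$race_ethnicity,
                 levels = c("white", setdiff(sort(unique(co$race_ethnicity)),
                                             "white")))
  oracle <- glm(co$lung_cancer_6yr ~ race, offset = off,
                family = binomial())
  got <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  want <- coef(oracle)
  expect_equal(unname(got["intercept_shift"]),
               unname(want["(Intercept)"]), tolerance = 1e-6)
  for (g in setdiff(levels(race), "white"))
    expect_equal(unname(got[g]), unname(want[paste0("race", g)]),
                 tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(oracle)),
               tolerance = 1e-6)
})

test_that("refitting dominates the base model in likelihood", {
  co <- generate_cohort(synthetic_spec(10000, seed = 8))
  base <- quiet_plco("original")
  fit <- fit_race_recalibration(co, base)
  lp0 <- linear_predictor(co, base)
  ll0 <- sum(dbinom(as.integer(co$lung_cancer_6yr), 1, plogis(lp0),
                    log = TRUE))
  expect_gte(fit$log_likelihood, ll0)
  # self-consistency: mean predicted risk tracks the event rate
  mu <- mean(compute_risk(co, fit$updated_model)$risk)
  expect_lt(abs(mu - mean(co$lung_cancer_6yr)) / mean(co$lung_cancer_6yr),
            0.05)
})

test_that("a race category with no events is flagged, not fatal", {
  co <- two_race_cohort(n_w = 80, ev_w = 8, n_a = 40, ev_a = 0)
  lat <- make_record(race_ethnicity = "latino")[rep(1, 40), ]
  lat$id <- paste0("l", 1:40)
  lat$lung_cancer_6yr <- 1:40 <= 6
  co <- rbind(co, lat)
  base <- quiet_plco("original")
  expect_warning(fit <- fit_race_recalibration(co, base), "separation")
  est <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  expect_true(is.na(est[["african_american"]]))
  expect_true(is.finite(est[["latino"]]))
  # updated model keeps the base coefficient for the separated category
  expect_equal(fit$updated_model$race_coefficients[["african_american"]],
               base$race_coefficients[["african_american"]])
})

test_that("cross-validation partitions are stratified and reproducible", {
  co <- generate_cohort(synthetic_spec(1000, seed = 13,
                                       target_incidence = 0.05))
  a <- crossfit_predictions(co, quiet_plco("original"), folds = 10,
                            seed = 99)
  b <- crossfit_predictions(co, quiet_plco("original"), folds = 10,
                            seed = 99)
  expect_identical(a, b)
  expect_false(any(is.na(a$risk)))
  expect_equal(a$id, co$id)  # every record scored exactly once, in order
  # fold sizes differ by at most one within each outcome stratum
  for (v in c(TRUE, FALSE)) {
    sizes <- table(a$fold[co$lung_cancer_6yr == v])
    expect_lte(diff(range(sizes)), 1)
  }
  c2 <- crossfit_predictions(co, quiet_plco("original"), folds = 10,
                             seed = 100)
  expect_false(identical(a$risk, c2$risk))
})

test_that("leave-one-out cross-fitting runs on a small cohort", {
  co <- two_race_cohort(n_w = 30, ev_w = 5, n_a = 20, ev_a = 4)
  oof <- crossfit_predictions(co, quiet_plco("original"), folds = 50,
                              seed = 2)
  expect_equal(nrow(oof), 50)
  expect_false(any(is.na(oof$risk)))
  expect_setequal(oof$fold, 1:50)
})
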