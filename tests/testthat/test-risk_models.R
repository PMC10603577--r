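test_that("packaged original model is the 11-predictor set", {
  m <- quiet_plco("original")
  # 10 covariate terms plus the race/ethnicity term = 11 predictors
  expect_equal(nrow(m$terms), 10)
  expect_setequal(names(m$race_coefficients), RACE_LEVELS)
  expect_equal(unname(m$race_coefficients["white"]), 0)
  expect_false(m$merged_race_variant)
})

test_that("coefficient files validate: ambiguous reference is fatal", {
  m <- quiet_plco("original")
  expect_error(
    coefficient_set("bad", m$intercept, m$terms,
                    replace(m$race_coefficients, "latino", 0)),
    "ambiguous reference")
  expect_error(
    coefficient_set("bad", m$intercept,
                    transform(m$terms, transformation = "square"),
                    m$race_coefficients),
    "unknown transformation")
})

test_that("toy coefficient files round-trip preserving term order", {
  terms <- data.frame(
    variable = c("duration", "age"),
    transformation = c("center_scale", "center"),
    center = c(5, 60), scale = c(2, NA), coefficient = c(0.3, -0.1))
  m <- coefficient_set("toy2", -3, terms, c(white = 0, latino = -0.2),
                       merged_race_variant = TRUE)
  path <- tempfile(fileext = ".yaml")
  write_coefficients(m, path)
  back <- suppressMessages(load_coefficients(path))
  expect_equal(back$terms$variable, c("duration", "age"))
  expect_equal(back$terms$coefficient, c(0.3, -0.1))
  expect_equal(back$intercept, -3)
  expect_true(back$merged_race_variant)
})

test_that("risk equals the logistic of the linear predictor", {
  m <- toy_model(intercept = -4)
  sc <- compute_risk(make_record(), m)
  expect_equal(sc$risk, 1 / (1 + exp(4)), tolerance = 1e-12)
  # record at all term centers, reference race: risk = logistic(intercept)
  plco <- quiet_plco("original")
  at_center <- make_record(age = 62, education = 4, bmi = 27,
                           smoking_status = "former",
                           intensity = 10 / 0.4021541613, duration = 27,
                           quit_years = 10)
  sc <- compute_risk(at_center, plco)
  expect_equal(sc$risk, plogis(plco$intercept), tolerance = 1e-12)
})

test_that("packaged model matches a hand-computed arithmetic oracle", {
  rec <- make_record(race_ethnicity = "african_american", age = 65,
                     education = 2, bmi = 31, copd_emphysema = TRUE,
                     family_history_lung_cancer = TRUE,
                     smoking_status = "current", intensity = 25,
                     duration = 40, quit_years = 0)
  # term-by-term sum written out independently of the evaluator
  lp_hand <- -4.532506 +
    0.0778868 * (65 - 62) +
    -0.0812744 * (2 - 4) +
    -0.0274194 * (31 - 27) +
    0.3553063 * 1 +
    0.4589971 * 0 +
    0.587185 * 1 +
    0.2597431 * 1 +
    -1.822606 * ((25 / 10)^(-1) - 0.4021541613) +
    0.0317321 * (40 - 27) +
    -0.0308572 * (0 - 10) +
    0.3944778
  sc <- compute_risk(rec, quiet_plco("original"))
  expect_equal(sc$linear_predictor, lp_hand, tolerance = 1e-10)
  expect_equal(sc$risk, 1 / (1 + exp(-lp_hand)), tolerance = 1e-10)
})

test_that("non-positive intensity is fatal under the reciprocal transform", {
  expect_error(compute_risk(make_record(intensity = 0,
                                        pack_years = 10),
                            quiet_plco("original")),
               "non-positive")
})

test_that("risk is monotone in predictors with positive coefficients", {
  m <- quiet_plco("original")
  base <- make_record()
  for (dur in c(10, 20, 30, 40)) {
    r1 <- compute_risk(make_record(duration = dur), m)$risk
    r2 <- compute_risk(make_record(duration = dur + 5), m)$risk
    expect_gt(r2, r1)
  }
  # quit-years enters negatively: longer abstinence, lower risk
  r1 <- compute_risk(make_record(quit_years = 5), m)$risk
  r2 <- compute_risk(make_record(quit_years = 14), m)$risk
  expect_lt(r2, r1)
})

test_that("logit/logistic round-trip holds to 1e-12 across the lp range", {
  lp <- seq(-20, 20, by = 0.5)
  expect_equal(qlogis(plogis(lp, log.p = TRUE), log.p = TRUE), lp,
               tolerance = 1e-12)
  # on the probability scale the identity is exact below 1/2, the regime
  # of 6-year absolute risks
  neg <- seq(-20, 0, by = 0.5)
  expect_equal(qlogis(plogis(neg)), neg, tolerance = 1e-12)
  m <- toy_model()
  sc <- compute_risk(make_record(), m)
  expect_equal(qlogis(sc$risk), sc$linear_predictor, tolerance = 1e-12)
})

test_that("race3l mapping merges the three groups into the reference", {
  recs <- make_cohort(
    make_record(id = "1", race_ethnicity = "nhpi"),
    make_record(id = "2", race_ethnicity = "japanese_american"),
    make_record(id = "3", race_ethnicity = "latino"),
    make_record(id = "4", race_ethnicity = "african_american"),
    make_record(id = "5", race_ethnicity = "white"))
  mapped <- map_race3l(recs)
  expect_equal(mapped$race_ethnicity,
               c("white", "white", "white", "african_american", "white"))
  # idempotent / fixed points
  expect_equal(map_race3l(mapped), mapped)
})

test_that("merged-race scoring equals original scoring after mapping", {
  m3 <- quiet_plco("race3l")
  recs <- make_cohort(
    make_record(id = "1", race_ethnicity = "nhpi", age = 70),
    make_record(id = "2", race_ethnicity = "latino", intensity = 5),
    make_record(id = "3", race_ethnicity = "african_american"),
    make_record(id = "4", race_ethnicity = "white"))
  # scoring unmapped records against the merged map is an error
  expect_error(compute_risk(recs, m3), "map_race3l")
  mapped <- map_race3l(recs)
  got <- compute_risk(mapped, m3)
  # oracle: original model restricted to the merged map scores identically
  orig <- quiet_plco("original")
  expect_equal(got$risk, compute_risk(mapped, orig)$risk,
               tolerance = 1e-12)
})
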