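# direct likelihood-ratio oracle for the two-group offset Poisson model
poisson_lr_p <- function(e1, i1, e2, i2) {
  ll <- function(lam1, lam2)
    dpois(e1, lam1 * i1, log = TRUE) + dpois(e2, lam2 * i2, log = TRUE)
  lam0 <- (e1 + e2) / (i1 + i2)
  lr <- 2 * (ll(e1 / i1, e2 / i2) - ll(lam0, lam0))
  pchisq(lr, df = 1, lower.tail = FALSE)
}

test_that("E-I ratios reproduce the published one-decimal values", {
  r <- ei_ratio(8771, 433)
  expect_equal(attr(r, "rounded"), 20.3)
  expect_equal(attr(ei_ratio(4115, 432), "rounded"), 9.5)
  expect_equal(attr(ei_ratio(2104, 125), "rounded"), 16.8)
  expect_equal(as.numeric(ei_ratio(100, 100)), 1.0)
  expect_error(ei_ratio(10, 0), "undefined")
})

test_that("percent differences follow the published formula", {
  expect_equal(percent_difference(9.5, 20.3), -53.2, tolerance = 0.05)
  expect_equal(round(percent_difference(16.8, 20.3), 1), -17.2)
  expect_equal(percent_difference(20.3, 20.3), 0)
  for (x in c(0.5, 1, 7.3, 19))
    expect_equal(percent_difference(x, x), 0)
})

test_that("Poisson comparison: null, antisymmetry, and headline contrast", {
  # identical ratios -> rate ratio 1, z = 0, p = 1
  p0 <- poisson_compare(100, 10, 50, 5)
  expect_equal(p0$rate_ratio, 1)
  expect_equal(p0$wald_z, 0)
  expect_equal(p0$p_value, 1)
  # swapping groups inverts the rate ratio and negates z, p unchanged
  a <- poisson_compare(8771, 433, 4115, 432)
  b <- poisson_compare(4115, 432, 8771, 433)
  expect_equal(a$rate_ratio, 1 / b$rate_ratio, tolerance = 1e-12)
  expect_equal(a$wald_z, -b$wald_z, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  # White vs African American under the 2021 rule: p < .001
  expect_lt(a$p_value, 0.001)
  expect_equal(a$rate_ratio, (4115 / 432) / (8771 / 433), tolerance = 1e-12)
})

test_that("Wald p tracks the likelihood-ratio oracle on small counts", {
  # small-count grid with moderate contrasts (rate ratio <= 2), where the
  # two asymptotic tests are expected to coincide
  for (i in c(2, 3, 5)) {
    for (e1 in c(5, 8, 10, 15, 20)) {
      for (e2 in c(5, 8, 10, 15, 20)) {
        if (e2 < e1 || e2 > 2 * e1) next
        w <- poisson_compare(e1, i, e2, i)$p_value
        lr <- poisson_lr_p(e1, i, e2, i)
        expect_lt(abs(w - lr) / lr, 0.20)
      }
    }
  }
  # the worked small-count case: (5,2) vs (10,2)
  expect_lt(abs(poisson_compare(5, 2, 10, 2)$p_value -
                  poisson_lr_p(5, 2, 10, 2)) / poisson_lr_p(5, 2, 10, 2),
            0.20)
})

test_that("screening performance arithmetic", {
  perf <- screening_performance(3, 4, 2, 6, 5)
  expect_equal(perf$sensitivity, 75)
  expect_equal(perf$specificity, (6 - 2) / 6 * 100, tolerance = 1e-12)
  expect_equal(perf$nns, 5 / 3, tolerance = 1e-12)
  # all cases eligible -> sensitivity 100%
  expect_equal(screening_performance(4, 4, 0, 6, 4)$sensitivity, 100)
  # NNS * sensitivity * total cases = eligible total, before rounding
  expect_equal(perf$nns * perf$sensitivity / 100 * 4, 5, tolerance = 1e-12)
})

test_that("published NNS values follow from eligible totals and sensitivity", {
  # 2021 rule: 57.7% of 1464 cases eligible, 25282 eligible in total
  nns21 <- screening_performance(round(0.577 * 1464), 1464,
                                 0, 103797, 25282)
  expect_equal(nns21$nns_rounded, 30L)
  # risk-based: 67.2% sensitivity, 25284 eligible in total
  nnsrb <- screening_performance(round(0.672 * 1464), 1464,
                                 0, 103797, 25284)
  expect_equal(nnsrb$nns_rounded, 26L)
})

test_that("disparity table reproduces the published comparisons", {
  res <- disparity_table(fixture_counts())
  row <- function(g, cr) res[res$group == g & res$criterion == cr, ]
  expect_equal(row("white", "uspstf_2021")$ei_ratio_rounded, 20.3)
  expect_equal(row("african_american", "uspstf_2021")$ei_ratio_rounded,
               9.5)
  expect_equal(round(row("african_american",
                         "uspstf_2021")$percent_difference), -53)
  expect_equal(round(row("nhpi", "uspstf_2021")$percent_difference, 1),
               -17.2)
  expect_equal(row("japanese_american", "plco_update")$ei_ratio_rounded,
               18.5)
  expect_equal(row("latino", "plco_update")$ei_ratio_rounded, 16.0)
  expect_equal(row("nhpi", "plco_update")$ei_ratio_rounded, 16.6)
  expect_equal(row("white", "plco_update")$ei_ratio_rounded, 18.4)
  expect_equal(row("african_american", "plco_update")$ei_ratio_rounded,
               15.9)
  # reference rows: zero percent difference, unit rate ratio
  expect_equal(row("white", "uspstf_2021")$percent_difference, 0)
  expect_equal(row("white", "uspstf_2021")$rate_ratio, 1)
  # Bonferroni-flagged significance for the headline contrasts
  expect_true(row("african_american", "uspstf_2021")$significant)
  expect_true(row("nhpi", "uspstf_2021")$significant)
  expect_lt(row("african_american", "uspstf_2021")$p_value, 0.001)
})

test_that("a single-group table yields one row and no comparison", {
  counts <- group_counts(c("latino", "overall"), c(100, 100), c(10, 10),
                         list(rule = c(40, 40)))
  res <- disparity_table(counts)
  expect_equal(nrow(res), 1)
  expect_true(is.na(res$p_value))
})
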