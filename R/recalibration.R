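# Constrained recalibration: re-estimate only the race/ethnicity-related
# parameters (an intercept shift plus per-race coefficients against the
# reference) of a coefficient set on a target cohort, keeping every other
# parameter frozen via a fixed offset. Exact MLE by iteratively
# reweighted least squares on the tiny (1 + R - 1)-dimensional problem.

#' Re-estimate race/ethnicity parameters on a cohort
#'
#' Maximizes the Bernoulli likelihood of the 6-year outcome on
#' `offset + delta0 + sum_r delta_r 1[race = r]`, where the offset is the
#' base model's full linear predictor minus its race term. The reference
#' race (the base model's zero-coefficient category) keeps `delta_r = 0`;
#' the intercept shift `delta0` is included so calibration can improve for
#' the reference group as well. Newton/IRLS iterations to a gradient-norm
#' tolerance.
#'
#' Race categories exhibiting separation (zero or all events) are flagged:
#' their records are excluded from the fit, their estimate is reported as
#' non-finite, and the updated model keeps the base coefficient for them.
#'
#' @param cohort Data.frame of participant records with `lung_cancer_6yr`.
#' @param base_model A `coefficient_set`.
#' @param tol Gradient max-norm convergence tolerance. Default 1e-8.
#' @param max_iter Maximum Newton iterations. Default 100.
#' @return A list of class `recalibration_result`: `updated_model`
#'   (differs from the base only in intercept and race coefficients),
#'   `estimates` (data.frame of parameter, estimate, se), `n_iterations`,
#'   `converged`, `log_likelihood`, `separated` (flagged categories).
#' @export
fit_race_recalibration <- function(cohort, base_model, tol = 1e-8,
                                   max_iter = 100L) {
  y <- as.integer(cohort$lung_cancer_6yr)
  race <- as.character(cohort$race_ethnicity)
  present <- intersect(names(base_model$race_coefficients), unique(race))
  if (length(present) < 2)
    stop("recalibration needs at least 2 race categories in the cohort")
  reference <- names(base_model$race_coefficients)[
    base_model$race_coefficients == 0]
  fit_races <- setdiff(present, reference)

  ev <- vapply(fit_races, function(g) sum(y[race == g]), integer(1))
  nn <- vapply(fit_races, function(g) sum(race == g), integer(1))
  separated <- fit_races[ev == 0L | ev == nn]
  fit_races <- setdiff(fit_races, separated)
  if (length(separated))
    warning("separation in race categories (estimate non-finite): ",
            paste(separated, collapse = ", "))

  keep <- !(race %in% separated)
  offset <- linear_predictor(cohort, base_model, include_race = FALSE)[keep]
  yk <- y[keep]
  X <- matrix(1, nrow = sum(keep), ncol = 1)
  for (g in fit_races) X <- cbind(X, as.numeric(race[keep] == g))
  colnames(X) <- c("intercept_shift", fit_races)
  p <- ncol(X)

  loglik <- function(b) {
    eta <- offset + drop(X %*% b)
    sum(yk * eta - log1p(exp(pmin(eta, 700))))
  }
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- offset + drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, yk - mu))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) { iter <- max_iter; break }
    W <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * W)
    delta <- solve(H, grad)
    # step-halving keeps Newton from overshooting on extreme offsets
    ll0 <- loglik(beta)
    step <- 1
    for (h in 1:30) {
      if (loglik(beta + step * delta) >= ll0 - 1e-12) break
      step <- step / 2
    }
    beta <- beta + step * delta
  }
  eta <- offset + drop(X %*% beta)
  mu <- stats::plogis(eta)
  H <- crossprod(X, X * (mu * (1 - mu)))
  se <- sqrt(diag(solve(H)))
  ll <- sum(stats::dbinom(yk, 1, mu, log = TRUE))

  est <- data.frame(parameter = colnames(X), estimate = beta, se = se,
                    stringsAsFactors = FALSE)
  if (length(separated))
    est <- rbind(est, data.frame(parameter = separated,
                                 estimate = NA_real_, se = NA_real_))
  rownames(est) <- NULL

  updated <- base_model
  updated$model_name <- paste0(base_model$model_name, "_update")
  updated$intercept <- base_model$intercept + unname(beta[1])
  rc <- base_model$race_coefficients
  rc[fit_races] <- beta[-1][match(fit_races, colnames(X)[-1])]
  updated$race_coefficients <- rc

  structure(list(updated_model = updated, estimates = est,
                 n_iterations = iter, converged = converged,
                 log_likelihood = ll, reference = reference,
                 separated = separated),
            class = "recalibration_result")
}

#' @export
print.recalibration_result <- function(x, ...) {
  cat(sprintf("<recalibration_result> %s: %s in %d iterations, logLik %.2f\n",
              x$updated_model$model_name,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$log_likelihood))
  print(x$estimates)
  invisible(x)
}

# outcome-stratified fold assignment, deterministic given seed; labels
# cycle across strata so fold sizes are balanced both within each stratum
# and globally (folds = n gives leave-one-out)
.stratified_folds <- function(outcome, folds, seed) {
  set.seed(seed)
  fold <- integer(length(outcome))
  start <- 0L
  for (v in c(TRUE, FALSE)) {
    idx <- which(outcome == v)
    fold[idx] <- (sample(seq_along(idx)) - 1L + start) %% folds + 1L
    start <- (start + length(idx)) %% folds
  }
  fold
}

#' Out-of-fold recalibrated risk predictions
#'
#' Cross-validation harness for the recalibration: partitions the cohort
#' into outcome-stratified folds (deterministic given the seed; fold sizes
#' within each outcome stratum differ by at most one), fits the race
#' recalibration on all but one fold, and scores the held-out fold with
#' the updated model. Every record is scored exactly once.
#'
#' @param cohort Data.frame of participant records.
#' @param base_model A `coefficient_set`.
#' @param folds Number of folds (>= 2). Default 10.
#' @param seed Seed for the fold partition.
#' @return Data.frame in cohort order: `id`, `fold`, `linear_predictor`,
#'   `risk`.
#' @export
crossfit_predictions <- function(cohort, base_model, folds = 10L,
                                 seed = 1L) {
  stopifnot(folds >= 2, folds <= nrow(cohort))
  y <- as.logical(cohort$lung_cancer_6yr)
  fold <- .stratified_folds(y, folds, seed)
  # a training set without events cannot be fit: refold once, else fatal
  train_events <- vapply(seq_len(folds), function(k)
    sum(y[fold != k]), integer(1))
  if (any(train_events == 0L)) {
    warning("a training fold lacked events; refolding once")
    fold <- .stratified_folds(y, folds, seed + 1L)
    train_events <- vapply(seq_len(folds), function(k)
      sum(y[fold != k]), integer(1))
    if (any(train_events == 0L))
      stop("cross-validation infeasible: a training fold has no events")
  }
  out <- data.frame(id = cohort$id, fold = fold,
                    linear_predictor = NA_real_, risk = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(folds)) {
    test <- fold == k
    fit <- suppressWarnings(
      fit_race_recalibration(cohort[!test, , drop = FALSE], base_model))
    sc <- compute_risk(cohort[test, , drop = FALSE], fit$updated_model)
    out$linear_predictor[test] <- sc$linear_predictor
    out$risk[test] <- sc$risk
  }
  out
}
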