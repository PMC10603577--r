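# Synthetic multiethnic cohort generator. Per-race covariate marginals
# default to the enrollment characteristics of a large California/Hawaii
# cohort of adults aged 45-75 with a smoking history; outcomes are drawn
# from a known coefficient-set "true" model whose intercept is tuned so
# the realized 6-year incidence matches a target (default 1.4%).

# per-race default marginals (means/SDs/proportions at enrollment)
.race_defaults <- function() {
  df <- data.frame(
    race = RACE_LEVELS,
    mix = c(0.183, 0.259, 0.203, 0.079, 0.276),
    age_mean = c(61.0, 60.6, 59.9, 56.2, 59.1),
    age_sd = c(8.9, 8.9, 7.6, 8.4, 9.0),
    p_female = c(0.555, 0.325, 0.345, 0.507, 0.486),
    p_current = c(0.375, 0.241, 0.289, 0.380, 0.276),
    bmi_mean = c(28.2, 24.9, 27.8, 29.1, 26.2),
    bmi_sd = c(5.7, 3.7, 4.8, 6.3, 4.9),
    intensity_mean = c(12.5, 16.0, 11.0, 15.9, 17.6),
    intensity_sd = c(7.1, 8.0, 7.3, 8.2, 8.7),
    duration_mean = c(23.6, 22.6, 20.5, 23.1, 22.9),
    duration_sd = c(12.3, 12.2, 13.0, 12.0, 12.6),
    quit_mean = c(7.6, 10.8, 9.3, 7.9, 10.1),
    p_cancer_history = c(0.100, 0.071, 0.062, 0.076, 0.116),
    p_family_history = c(0.063, 0.068, 0.040, 0.076, 0.077),
    p_copd = c(0.08, 0.08, 0.08, 0.08, 0.08),
    stringsAsFactors = FALSE)
  edu <- rbind(
    african_american = c(15.1, 27.8, 6.3, 30.9, 10.4, 9.5),
    japanese_american = c(8.7, 30.4, 13.2, 19.0, 17.8, 10.8),
    latino = c(43.4, 24.1, 6.7, 16.3, 4.9, 4.7),
    nhpi = c(14.5, 42.3, 7.8, 21.6, 8.0, 5.8),
    white = c(7.1, 21.2, 4.5, 29.5, 18.3, 19.4))
  edu <- edu / rowSums(edu)
  list(params = df, education = edu)
}

#' Specify a synthetic multiethnic cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. Defaults
#' emulate the enrollment marginals of a multiethnic cohort of adults aged
#' 45 to 75 with a smoking history: race mix, per-race age, sex, education,
#' BMI, comorbidity-flag prevalences, smoking status, intensity, duration,
#' and quit-years distributions, with an overall 6-year lung cancer
#' incidence near 1.4%.
#'
#' @param n Cohort size.
#' @param seed RNG seed (cohorts are byte-identical given the same spec
#'   and seed).
#' @param race_mix Named probability vector over [RACE_LEVELS]; must sum
#'   to 1.
#' @param params Per-race marginal parameters (data.frame as returned in
#'   the default spec); rarely overridden wholesale.
#' @param education Per-race 6-level education probability matrix.
#' @param age_range Truncation bounds for age. Default `c(45, 75)`.
#' @param true_model `coefficient_set` used as the data-generating risk
#'   model. Default: the packaged original model.
#' @param target_incidence Desired overall expected 6-year incidence; the
#'   true model's intercept is shifted (bisection) so the cohort's mean
#'   risk matches it. Default 0.014.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n, seed = 1L, race_mix = NULL, params = NULL,
                           education = NULL, age_range = c(45, 75),
                           true_model = NULL, target_incidence = 0.014) {
  d <- .race_defaults()
  if (is.null(params)) params <- d$params
  if (is.null(education)) education <- d$education
  if (!is.null(race_mix)) {
    stopifnot(all(names(race_mix) %in% RACE_LEVELS))
    params$mix <- unname(race_mix[params$race])
  }
  if (abs(sum(params$mix) - 1) > 1e-9) stop("race_mix must sum to 1")
  sd_cols <- grep("_sd$", names(params), value = TRUE)
  if (any(as.matrix(params[sd_cols]) <= 0)) stop("all SDs must be positive")
  p_cols <- grep("^p_|^mix$", names(params), value = TRUE)
  if (any(as.matrix(params[p_cols]) < 0 | as.matrix(params[p_cols]) > 1))
    stop("probabilities must lie in [0,1]")
  if (is.null(true_model)) true_model <- plco_model("original")
  stopifnot(target_incidence > 0, target_incidence < 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 params = params, education = education,
                 age_range = age_range, true_model = true_model,
                 target_incidence = target_incidence),
            class = "synthetic_spec")
}

# inverse-CDF truncated normal; deterministic under the current RNG stream
.rtnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws participant records from the spec's per-race marginals
#' (truncated normals for age/BMI/intensity/duration, exponential
#' quit-years for former smokers truncated at age - 18 - duration,
#' categorical education), derives pack-years as intensity/20 times
#' duration, and assigns the 6-year outcome as Bernoulli of the true
#' model's risk after shifting the model intercept so the cohort's
#' expected incidence equals the target.
#'
#' @param spec A `synthetic_spec`.
#' @return Data.frame of participant records with attribute
#'   `intercept_shift` (the tuned offset applied to the true model's
#'   intercept).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n
  empty <- as.data.frame(
    stats::setNames(rep(list(logical(0)), length(COHORT_COLUMNS)),
                    COHORT_COLUMNS))
  if (n == 0L) return(empty)
  set.seed(spec$seed)
  p <- spec$params

  ri <- sample.int(nrow(p), n, replace = TRUE, prob = p$mix)
  age <- .rtnorm(n, p$age_mean[ri], p$age_sd[ri],
                 spec$age_range[1], spec$age_range[2])
  sex <- ifelse(stats::runif(n) < p$p_female[ri], "female", "male")
  edu_cum <- t(apply(spec$education, 1, cumsum))
  edu <- 1L + rowSums(stats::runif(n) >
                        edu_cum[match(p$race[ri], rownames(edu_cum)), ,
                                drop = FALSE])
  edu <- pmin(edu, 6L)
  bmi <- .rtnorm(n, p$bmi_mean[ri], p$bmi_sd[ri], 15, 60)
  copd <- stats::runif(n) < p$p_copd[ri]
  cancer <- stats::runif(n) < p$p_cancer_history[ri]
  famhx <- stats::runif(n) < p$p_family_history[ri]
  current <- stats::runif(n) < p$p_current[ri]

  intensity <- .rtnorm(n, p$intensity_mean[ri], p$intensity_sd[ri], 1, 80)
  duration <- pmin(.rtnorm(n, p$duration_mean[ri], p$duration_sd[ri], 1, 70),
                   pmax(age - 18, 1))
  quit_cap <- pmax(age - 18 - duration, 0.5)
  quit <- ifelse(current, 0,
                 pmin(stats::rexp(n, rate = 1 / p$quit_mean[ri]), quit_cap))
  quit[!current] <- pmax(quit[!current], 0.1)
  pack_years <- intensity / 20 * duration

  cohort <- data.frame(
    id = sprintf("s%06d", seq_len(n)),
    race_ethnicity = p$race[ri], age = age, sex = sex, education = edu,
    bmi = bmi, copd_emphysema = copd, personal_cancer_history = cancer,
    family_history_lung_cancer = famhx,
    smoking_status = ifelse(current, "current", "former"),
    intensity = intensity, duration = duration, quit_years = quit,
    pack_years = pack_years, lung_cancer_6yr = NA,
    stringsAsFactors = FALSE)

  lp <- linear_predictor(cohort, spec$true_model)
  f <- function(c0) mean(stats::plogis(lp + c0)) - spec$target_incidence
  if (f(-15) > 0 || f(15) < 0)
    stop("target incidence infeasible: cannot bracket the intercept shift ",
         sprintf("(mean risk range %.4g..%.4g, target %.4g)",
                 mean(stats::plogis(lp - 15)), mean(stats::plogis(lp + 15)),
                 spec$target_incidence))
  shift <- stats::uniroot(f, c(-15, 15), tol = 1e-10)$root
  cohort$lung_cancer_6yr <- stats::runif(n) < stats::plogis(lp + shift)
  attr(cohort, "intercept_shift") <- shift
  cohort
}

#' Shifted copy of a coefficient set
#'
#' Returns the model with a constant added to its intercept, e.g. the
#' tuned data-generating model of a synthetic cohort.
#'
#' @param model A `coefficient_set`.
#' @param shift Constant added to the intercept (logit scale).
#' @param name Optional new model name.
#' @return A `coefficient_set`.
#' @export
shift_intercept <- function(model, shift, name = model$model_name) {
  model$intercept <- model$intercept + shift
  model$model_name <- name
  model
}

#' Aggregate a cohort into a group counts table
#'
#' Bridges individual-level records to the per-group counts shape: group
#' sizes, 6-year incident case counts, and (optionally) eligible counts
#' under each supplied criterion.
#'
#' @param cohort Data.frame of participant records.
#' @param criteria List of `eligibility_criterion` objects (possibly
#'   empty).
#' @param scores Data.frame from [compute_risk()], required when any
#'   criterion is risk-based; rows aligned with `cohort`.
#' @return A `group_counts` object (groups present in the cohort get their
#'   observed counts; absent groups get zero rows).
#' @export
aggregate_counts <- function(cohort, criteria = list(), scores = NULL) {
  groups <- c(RACE_LEVELS, "overall")
  tab <- function(x) {
    per <- vapply(RACE_LEVELS, function(g)
      sum(x[cohort$race_ethnicity == g]), numeric(1))
    c(per, overall = sum(per))
  }
  n_total <- tab(rep(1L, nrow(cohort)))
  cases <- tab(as.integer(cohort$lung_cancer_6yr))
  eligible <- list()
  for (cr in criteria) {
    e <- is_eligible(cohort, cr, scores)
    eligible[[cr$name]] <- tab(as.integer(e))
  }
  group_counts(groups, n_total, cases, eligible)
}
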