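# Eligibility-incidence (E-I) ratio disparity analysis and screening
# performance metrics. The E-I ratio of a group is the number of
# screening-eligible participants divided by the number of 6-year incident
# lung cancer cases in the group (cases need not be eligible); a lower
# ratio flags a group under-served by the criterion relative to its risk.

# round half away from zero, as results tables print
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Eligibility-incidence ratio
#'
#' @param eligible Number of screening-eligible participants (E).
#' @param cases Number of incident lung cancer cases (I); must be
#'   positive, else the ratio is undefined.
#' @return The raw ratio E/I, with attribute `rounded` (one decimal, half
#'   away from zero).
#' @export
ei_ratio <- function(eligible, cases) {
  if (any(cases <= 0)) stop("E-I ratio undefined: no incident cases")
  r <- eligible / cases
  attr(r, "rounded") <- round_half_away(r, 1L)
  r
}

#' Percent difference of E-I ratios against a reference group
#'
#' `(group - reference) / reference * 100`. Upstream the ratios are
#' rounded to one decimal, which is the scale on which results tables
#' print the differences.
#'
#' @param group_ratio E-I ratio of the compared group.
#' @param reference_ratio E-I ratio of the reference group.
#' @return Percent difference (negative = lower than reference).
#' @export
percent_difference <- function(group_ratio, reference_ratio) {
  (group_ratio - reference_ratio) / reference_ratio * 100
}

#' Two-group Poisson comparison of E-I ratios
#'
#' Closed-form Poisson regression for the eligible counts of two groups
#' with the log of incident cases as offset: the rate ratio is
#' `(e2/i2) / (e1/i1)`, the standard error of its log is
#' `sqrt(1/e1 + 1/e2)`, and a two-sided Wald p-value is reported.
#'
#' @param e1,i1 Eligible and incident-case counts of the first
#'   (reference) group.
#' @param e2,i2 Eligible and incident-case counts of the second group.
#' @return List: `rate_ratio`, `se_log_rr`, `wald_z`, `p_value`.
#' @export
poisson_compare <- function(e1, i1, e2, i2) {
  if (any(c(i1, i2) <= 0)) stop("incident case counts must be positive")
  if (any(c(e1, e2) == 0)) {
    warning("zero eligible count; using a 0.5 continuity adjustment")
    e1 <- e1 + 0.5; e2 <- e2 + 0.5
  }
  rr <- (e2 / i2) / (e1 / i1)
  se <- sqrt(1 / e1 + 1 / e2)
  z <- log(rr) / se
  list(rate_ratio = rr, se_log_rr = se, wald_z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Screening performance metrics
#'
#' Sensitivity (eligible cases among all cases), specificity (ineligible
#' non-cases among all non-cases), and the number needed to screen to
#' detect one lung cancer (eligible participants per eligible case),
#' reported raw and rounded to the nearest integer.
#'
#' @param eligible_cases Screening-eligible incident cases.
#' @param total_cases All incident cases.
#' @param eligible_noncases Screening-eligible non-cases.
#' @param total_noncases All non-cases.
#' @param eligible_total All screening-eligible participants.
#' @return List of class `performance_result`: `sensitivity` and
#'   `specificity` (percent), `nns`, `nns_rounded`.
#' @export
screening_performance <- function(eligible_cases, total_cases,
                                  eligible_noncases, total_noncases,
                                  eligible_total) {
  stopifnot(eligible_cases <= total_cases,
            eligible_noncases <= total_noncases)
  structure(list(
    sensitivity = eligible_cases / total_cases * 100,
    specificity = (total_noncases - eligible_noncases) /
      total_noncases * 100,
    nns = if (eligible_cases > 0) eligible_total / eligible_cases
          else NA_real_,
    nns_rounded = if (eligible_cases > 0)
      as.integer(round_half_away(eligible_total / eligible_cases))
      else NA_integer_),
    class = "performance_result")
}

#' @export
print.performance_result <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%, specificity %.1f%%, NNS %.2f (~%d)\n",
              x$sensitivity, x$specificity, x$nns, x$nns_rounded))
  invisible(x)
}

#' E-I ratio disparity table
#'
#' For every group and criterion in a group counts table: the E-I ratio
#' (raw and one-decimal rounded), the percent difference of the rounded
#' ratio against the reference group, and the Poisson rate-ratio Wald test
#' against the reference, flagged for significance after Bonferroni
#' correction over the non-reference comparisons.
#'
#' @param counts A `group_counts` object.
#' @param config An [analysis_config()] (reference group, per-test
#'   alpha).
#' @return Data.frame of class `ei_results`, one row per group x
#'   criterion: `group`, `criterion`, `eligible`, `incident_cases`,
#'   `ei_ratio`, `ei_ratio_rounded`, `percent_difference`, `rate_ratio`,
#'   `wald_z`, `p_value`, `significant`.
#' @export
disparity_table <- function(counts, config = analysis_config()) {
  ref <- config$reference_group
  groups <- setdiff(rownames(counts), "overall")
  have_ref <- ref %in% groups && counts[ref, "incident_cases_6yr"] > 0
  rows <- list()
  for (cr in criteria_names(counts)) {
    ec <- paste0("eligible.", cr)
    if (have_ref) {
      e_ref <- counts[ref, ec]
      i_ref <- counts[ref, "incident_cases_6yr"]
      r_ref <- round_half_away(e_ref / i_ref, 1L)
    }
    for (g in groups) {
      e <- counts[g, ec]; i <- counts[g, "incident_cases_6yr"]
      if (i == 0 || counts[g, "n_total"] == 0) next
      r <- ei_ratio(e, i)
      if (have_ref && g != ref) {
        pc <- poisson_compare(e_ref, i_ref, e, i)
        pd <- percent_difference(attr(r, "rounded"), r_ref)
        sig <- pc$p_value < config$per_test_alpha
      } else if (have_ref) {
        pc <- list(rate_ratio = 1, wald_z = 0, p_value = NA_real_)
        pd <- 0; sig <- NA
      } else {
        pc <- list(rate_ratio = NA_real_, wald_z = NA_real_,
                   p_value = NA_real_)
        pd <- NA_real_; sig <- NA
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, criterion = cr, eligible = e, incident_cases = i,
        ei_ratio = as.numeric(r), ei_ratio_rounded = attr(r, "rounded"),
        percent_difference = pd, rate_ratio = pc$rate_ratio,
        wald_z = pc$wald_z, p_value = pc$p_value, significant = sig,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ei_results", "data.frame")
  out
}

#' Screening performance table from individual records
#'
#' Computes [screening_performance()] per group and overall for each
#' criterion, from a cohort and its per-criterion eligibility.
#'
#' @param cohort Data.frame of participant records.
#' @param criteria List of `eligibility_criterion` objects.
#' @param scores [compute_risk()] output aligned with the cohort (needed
#'   for risk criteria).
#' @return Data.frame: `group`, `criterion`, `eligible`, `cases`,
#'   `eligible_cases`, `sensitivity`, `specificity`, `nns`,
#'   `nns_rounded`.
#' @export
performance_table <- function(cohort, criteria, scores = NULL) {
  y <- as.logical(cohort$lung_cancer_6yr)
  rows <- list()
  for (cr in criteria) {
    e <- is_eligible(cohort, cr, scores)
    for (g in c(intersect(RACE_LEVELS, unique(cohort$race_ethnicity)),
                "overall")) {
      sel <- if (g == "overall") rep(TRUE, length(y))
             else cohort$race_ethnicity == g
      tc <- sum(y[sel]); tn <- sum(!y[sel])
      if (tc == 0 || tn == 0) next
      perf <- screening_performance(sum(e[sel] & y[sel]), tc,
                                    sum(e[sel] & !y[sel]), tn,
                                    sum(e[sel]))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, criterion = cr$name, eligible = sum(e[sel]),
        cases = tc, eligible_cases = sum(e[sel] & y[sel]),
        sensitivity = perf$sensitivity, specificity = perf$specificity,
        nns = perf$nns, nns_rounded = perf$nns_rounded,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
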