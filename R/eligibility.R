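# Screening eligibility: age/smoking rules (USPSTF 2013/2021) and
# risk-threshold criteria, plus eligibility-matched threshold selection.

#' Construct an age/smoking-history eligibility rule
#'
#' A rule criterion deems a participant eligible when age lies in the
#' inclusive range, pack-years meet the minimum, and the participant
#' currently smokes or quit within the maximum number of years.
#'
#' @param name Criterion name.
#' @param age_range Inclusive age range `c(lo, hi)`.
#' @param min_pack_years Minimum cumulative pack-years.
#' @param max_quit_years Maximum years since cessation for former smokers.
#' @return An `eligibility_criterion` of kind `age_smoking_rule`.
#' @export
rule_criterion <- function(name, age_range, min_pack_years,
                           max_quit_years) {
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2])
  structure(list(name = name, kind = "age_smoking_rule",
                 age_range = age_range, min_pack_years = min_pack_years,
                 max_quit_years = max_quit_years),
            class = "eligibility_criterion")
}

#' USPSTF 2021 lung cancer screening criteria
#'
#' Age 50-80 years, at least 20 pack-years, current smoker or quit within
#' 15 years.
#' @return An `eligibility_criterion`.
#' @export
uspstf_2021 <- function() rule_criterion("uspstf_2021", c(50, 80), 20, 15)

#' USPSTF 2013 lung cancer screening criteria
#'
#' Age 55-80 years, at least 30 pack-years, current smoker or quit within
#' 15 years.
#' @return An `eligibility_criterion`.
#' @export
uspstf_2013 <- function() rule_criterion("uspstf_2013", c(55, 80), 30, 15)

#' Construct a risk-threshold eligibility criterion
#'
#' Eligible when predicted 6-year risk equals or exceeds the threshold
#' (inclusive) and age lies inside the age window (individuals outside the
#' window are ineligible regardless of risk).
#'
#' @param threshold Risk threshold in (0, 1); an infinite threshold is the
#'   "none eligible" sentinel returned by [match_threshold()] for a zero
#'   target.
#' @param name Criterion name. Default built from the threshold.
#' @param age_window Inclusive age window. Default `c(50, 80)`.
#' @param model_name Name of the risk model the scores come from
#'   (bookkeeping only).
#' @return An `eligibility_criterion` of kind `risk_threshold`.
#' @export
risk_criterion <- function(threshold, name = NULL,
                           age_window = c(50, 80), model_name = NA) {
  stopifnot(is.infinite(threshold) || (threshold > 0 && threshold < 1),
            length(age_window) == 2, age_window[1] < age_window[2])
  if (is.null(name)) name <- sprintf("risk_%.4g", threshold)
  structure(list(name = name, kind = "risk_threshold",
                 threshold = threshold, age_window = age_window,
                 model_name = model_name),
            class = "eligibility_criterion")
}

#' @export
print.eligibility_criterion <- function(x, ...) {
  if (x$kind == "age_smoking_rule")
    cat(sprintf("<criterion> %s: age %g-%g, >=%g pack-years, quit <=%g y\n",
                x$name, x$age_range[1], x$age_range[2], x$min_pack_years,
                x$max_quit_years))
  else
    cat(sprintf("<criterion> %s: 6-y risk >= %g, age %g-%g\n",
                x$name, x$threshold, x$age_window[1], x$age_window[2]))
  invisible(x)
}

#' Evaluate screening eligibility
#'
#' Applies one criterion to participant records. For rule criteria,
#' eligibility is age within the inclusive range AND pack-years at or
#' above the minimum AND (current smoker OR quit-years at or below the
#' maximum). For risk criteria, predicted risk at or above the threshold
#' (inclusive) AND age within the window.
#'
#' @param records Data.frame of participant records.
#' @param criterion An `eligibility_criterion`.
#' @param scores Data.frame from [compute_risk()] aligned with `records`
#'   (or a numeric risk vector); required iff the criterion is risk-based.
#' @return Logical vector, one element per record.
#' @export
is_eligible <- function(records, criterion, scores = NULL) {
  stopifnot(inherits(criterion, "eligibility_criterion"))
  if (criterion$kind == "age_smoking_rule") {
    if (any(is.na(records$pack_years)))
      stop("pack_years missing; derive before assessing eligibility")
    records$age >= criterion$age_range[1] &
      records$age <= criterion$age_range[2] &
      records$pack_years >= criterion$min_pack_years &
      (records$smoking_status == "current" |
         records$quit_years <= criterion$max_quit_years)
  } else {
    if (is.null(scores))
      stop("risk scores required for a risk_threshold criterion")
    risk <- if (is.data.frame(scores)) scores$risk else as.numeric(scores)
    if (length(risk) != nrow(records))
      stop("scores not aligned with records")
    risk >= criterion$threshold &
      records$age >= criterion$age_window[1] &
      records$age <= criterion$age_window[2]
  }
}

#' Eligibility-matched risk threshold
#'
#' Returns the largest threshold t such that at least `target_count`
#' records inside the age window have risk >= t: the `target_count`-th
#' largest in-window risk. With tied risks at the threshold the eligible
#' count may exceed the target (tie inflation). A zero target returns
#' `Inf` (none eligible).
#'
#' @param risks Numeric predicted risks (or a [compute_risk()] data.frame).
#' @param ages Ages aligned with `risks`.
#' @param target_count Number of eligible records to match.
#' @param age_window Inclusive age window. Default `c(50, 80)`.
#' @return Threshold probability (or `Inf`).
#' @export
match_threshold <- function(risks, ages, target_count,
                            age_window = c(50, 80)) {
  risk <- if (is.data.frame(risks)) risks$risk else as.numeric(risks)
  inw <- sort(risk[ages >= age_window[1] & ages <= age_window[2]],
              decreasing = TRUE)
  if (target_count == 0) return(Inf)
  if (target_count > length(inw))
    stop("target_count exceeds number of in-window records")
  inw[target_count]
}

#' Per-group eligibility summary
#'
#' Counts eligible participants per racial/ethnic group and overall for
#' each criterion; proportions (percent of group) are attached as
#' attribute `proportions`.
#'
#' @param cohort Data.frame of participant records.
#' @param criteria List of `eligibility_criterion` objects.
#' @param scores [compute_risk()] output aligned with `cohort` (needed for
#'   risk criteria).
#' @return A `group_counts` object with attribute `proportions` (matrix,
#'   percent of group eligible per criterion).
#' @export
eligibility_summary <- function(cohort, criteria, scores = NULL) {
  counts <- aggregate_counts(cohort, criteria, scores)
  elig_cols <- grep("^eligible\\.", names(counts), value = TRUE)
  prop <- sapply(elig_cols, function(cc)
    ifelse(counts$n_total > 0, counts[[cc]] / counts$n_total * 100, 0))
  prop <- matrix(prop, nrow = nrow(counts),
                 dimnames = list(rownames(counts),
                                 sub("^eligible\\.", "", elig_cols)))
  attr(counts, "proportions") <- prop
  counts
}
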