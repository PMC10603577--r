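# Domain types and delimited-text I/O shared by all pipeline stages.

#' Racial and ethnic groups of the multiethnic cohort
#'
#' Canonical lowercase tokens used throughout the package for the five
#' racial and ethnic groups represented in the cohort.
#' @export
RACE_LEVELS <- c("african_american", "japanese_american", "latino",
                 "nhpi", "white")

#' Canonical cohort column names
#'
#' Column names of a participant table as produced by [generate_cohort()]
#' and expected (after schema mapping) by [read_cohort()].
#' @export
COHORT_COLUMNS <- c("id", "race_ethnicity", "age", "sex", "education", "bmi",
                    "copd_emphysema", "personal_cancer_history",
                    "family_history_lung_cancer", "smoking_status",
                    "intensity", "duration", "quit_years", "pack_years",
                    "lung_cancer_6yr")

.bool_cols <- c("copd_emphysema", "personal_cancer_history",
                "family_history_lung_cancer", "lung_cancer_6yr")
.num_cols <- c("age", "education", "bmi", "intensity", "duration",
               "quit_years", "pack_years")

#' Analysis configuration
#'
#' Bundles the tuning constants of the disparity analysis: the reference
#' group for comparisons, the familywise alpha and Bonferroni-corrected
#' per-test alpha, the risk threshold(s) for risk-based eligibility, the
#' age window inside which risk-based eligibility applies, and the number
#' of cross-validation folds.
#'
#' @param reference_group Reference race/ethnicity for disparity
#'   comparisons. Default `"white"`.
#' @param alpha_familywise Familywise significance level. Default 0.05.
#' @param n_comparisons Number of pairwise group comparisons over which the
#'   Bonferroni correction is taken. Default 4 (each minoritized group vs
#'   the reference).
#' @param risk_thresholds Numeric vector of 6-year risk thresholds; the
#'   first element is the primary threshold (default 1.3%), the remainder a
#'   sensitivity grid.
#' @param age_window Inclusive age range (years) for risk-based
#'   eligibility. Default `c(50, 80)`.
#' @param cv_folds Number of cross-validation folds. Default 10.
#' @param rng_seed Root seed for all stochastic steps.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(reference_group = "white",
                            alpha_familywise = 0.05,
                            n_comparisons = 4,
                            risk_thresholds = c(0.013, 0.01, 0.0151,
                                                0.017, 0.02),
                            age_window = c(50, 80),
                            cv_folds = 10,
                            rng_seed = 1L) {
  stopifnot(reference_group %in% RACE_LEVELS,
            alpha_familywise > 0, alpha_familywise < 1,
            n_comparisons >= 1,
            all(risk_thresholds > 0), all(risk_thresholds < 1),
            length(age_window) == 2, age_window[1] < age_window[2],
            cv_folds >= 2)
  structure(list(reference_group = reference_group,
                 alpha_familywise = alpha_familywise,
                 n_comparisons = as.integer(n_comparisons),
                 per_test_alpha = alpha_familywise / n_comparisons,
                 risk_thresholds = risk_thresholds,
                 age_window = age_window,
                 cv_folds = as.integer(cv_folds),
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

# Row-level validation and repair. Returns list(cohort, rejected, repairs).
.validate_rows <- function(df) {
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  flag <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }

  flag(is.na(df$race_ethnicity) | !nzchar(as.character(df$race_ethnicity)),
       "missing_race")
  flag(!is.na(df$race_ethnicity) &
         !(as.character(df$race_ethnicity) %in% RACE_LEVELS),
       "unknown_race")
  flag(is.na(df$smoking_status) | !nzchar(as.character(df$smoking_status)),
       "missing_smoking")
  # study population is restricted to people with a smoking history
  flag(!is.na(df$smoking_status) &
         !(as.character(df$smoking_status) %in% c("current", "former")),
       "never_smoker")
  flag(is.na(df$age), "missing_age")
  smoking_incomplete <- (is.na(df$intensity) | is.na(df$duration)) &
    is.na(df$pack_years)
  flag(smoking_incomplete, "missing_smoking")
  flag(!is.na(df$intensity) & df$intensity <= 0, "nonpositive_intensity")
  flag(!is.na(df$duration) & df$duration < 0, "negative_duration")

  # pack-years must agree with (intensity/20)*duration within 15% relative
  derived <- df$intensity / 20 * df$duration
  have3 <- !is.na(df$pack_years) & !is.na(derived)
  incons <- have3 & derived > 0 &
    abs(df$pack_years - derived) / derived > 0.15
  flag(incons, "inconsistent_pack_years")

  keep <- is.na(reason)
  rejected <- data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  df <- df[keep, , drop = FALSE]
  derived <- derived[keep]

  repairs <- character(0)
  miss_py <- is.na(df$pack_years)
  if (any(miss_py)) {
    df$pack_years[miss_py] <- derived[miss_py]
    repairs <- c(repairs, sprintf("derived pack_years for %d rows",
                                  sum(miss_py)))
  }
  cur_quit <- df$smoking_status == "current" &
    !is.na(df$quit_years) & df$quit_years > 0
  if (any(cur_quit)) {
    df$quit_years[cur_quit] <- 0
    repairs <- c(repairs,
                 sprintf("reset quit_years to 0 for %d current smokers",
                         sum(cur_quit)))
  }
  fmr_zero <- df$smoking_status == "former" &
    (is.na(df$quit_years) | df$quit_years == 0)
  if (any(fmr_zero)) {
    df$smoking_status[fmr_zero] <- "current"
    df$quit_years[fmr_zero] <- 0
    repairs <- c(repairs,
                 sprintf("reclassified %d former smokers with zero quit_years as current",
                         sum(fmr_zero)))
  }
  miss_copd <- is.na(df$copd_emphysema)
  if (any(miss_copd)) {
    df$copd_emphysema[miss_copd] <- FALSE
    repairs <- c(repairs,
                 sprintf("imputed copd_emphysema = FALSE for %d rows",
                         sum(miss_copd)))
  }
  rownames(df) <- NULL
  list(cohort = df, rejected = rejected, repairs = repairs)
}

#' Read a participant cohort from delimited text
#'
#' Reads a cohort table (comma-separated by default, tab accepted),
#' optionally remapping file column names to the canonical set in
#' [COHORT_COLUMNS], validates every row, repairs repairable
#' inconsistencies (missing pack-years derived from intensity and duration;
#' current smokers with nonzero quit-years reset; missing COPD flags
#' imputed as `FALSE`), and drops rows that violate the record invariants.
#'
#' Rows are rejected, with a reason code, when race/ethnicity or smoking
#' data are missing or when the participant has no smoking history,
#' mirroring the exclusions applied when assembling a screening-eligible
#' study population.
#'
#' @param path Path to the delimited text file (header required, UTF-8,
#'   booleans as 0/1, categories as lowercase tokens).
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(age = "AGE_AT_ENTRY", race_ethnicity = "ethnic_grp")`.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A data.frame of validated participant records with attributes
#'   `rejected` (data.frame of row index and reason code) and `repairs`
#'   (character vector describing logged repairs).
#' @export
read_cohort <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           na.strings = c("", "NA"))
  if (!is.null(schema)) {
    bad <- setdiff(unname(schema), names(raw))
    if (length(bad))
      stop("schema refers to absent columns: ", paste(bad, collapse = ", "))
    names(raw)[match(unname(schema), names(raw))] <- names(schema)
  }
  missing_cols <- setdiff(setdiff(COHORT_COLUMNS, c("pack_years", "id")),
                          names(raw))
  if (length(missing_cols))
    stop("unresolvable columns: ", paste(missing_cols, collapse = ", "))
  if (!"id" %in% names(raw)) raw$id <- as.character(seq_len(nrow(raw)))
  if (!"pack_years" %in% names(raw)) raw$pack_years <- NA_real_
  raw$id <- as.character(raw$id)
  for (cc in .num_cols) raw[[cc]] <- as.numeric(raw[[cc]])
  for (cc in .bool_cols) raw[[cc]] <- as.logical(as.integer(raw[[cc]]))
  raw$race_ethnicity <- tolower(as.character(raw$race_ethnicity))
  raw$sex <- tolower(as.character(raw$sex))
  raw$smoking_status <- tolower(as.character(raw$smoking_status))
  raw <- raw[COHORT_COLUMNS]

  v <- .validate_rows(raw)
  if (nrow(v$rejected))
    message(sprintf("read_cohort: rejected %d of %d rows (%s)",
                    nrow(v$rejected), nrow(raw),
                    paste(sprintf("%s: %d",
                                  names(table(v$rejected$reason)),
                                  as.integer(table(v$rejected$reason))),
                          collapse = ", ")))
  for (r in v$repairs) message("read_cohort: ", r)
  structure(v$cohort, rejected = v$rejected, repairs = v$repairs)
}

#' Write a participant cohort to delimited text
#'
#' Writes the canonical columns as CSV with booleans encoded 0/1. The
#' writer enforces the quit-years convention: current smokers are written
#' with `quit_years = 0`.
#'
#' @param cohort Data.frame of participant records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[COHORT_COLUMNS]
  if (any(out$smoking_status == "current" & out$quit_years != 0))
    out$quit_years[out$smoking_status == "current"] <- 0
  for (cc in .bool_cols) out[[cc]] <- as.integer(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a group counts table
#'
#' A `group_counts` object holds per-group aggregates in the shape of a
#' cohort characteristics table: for each racial/ethnic group and for the
#' pooled cohort, the group size, the number of 6-year incident lung cancer
#' cases, and the number of screening-eligible participants under each
#' criterion.
#'
#' @param groups Character vector of group labels (the overall row is
#'   labelled `"overall"`).
#' @param n_total Integer vector of group sizes.
#' @param incident_cases_6yr Integer vector of 6-year incident case counts.
#' @param eligible Named list (criterion name -> integer vector) of
#'   eligible counts, or `NULL`.
#' @return A data.frame of class `group_counts` with row names = groups,
#'   columns `n_total`, `incident_cases_6yr`, and one `eligible.<criterion>`
#'   column per criterion.
#' @export
group_counts <- function(groups, n_total, incident_cases_6yr,
                         eligible = NULL) {
  df <- data.frame(n_total = as.integer(n_total),
                   incident_cases_6yr = as.integer(incident_cases_6yr),
                   row.names = groups, check.names = FALSE)
  for (crit in names(eligible))
    df[[paste0("eligible.", crit)]] <- as.integer(eligible[[crit]])
  .check_group_counts(df)
  class(df) <- c("group_counts", "data.frame")
  df
}

.check_group_counts <- function(df) {
  if (!"overall" %in% rownames(df)) stop("group_counts needs an overall row")
  if (any(df$incident_cases_6yr < 0 | df$incident_cases_6yr > df$n_total))
    stop("incident_cases_6yr outside [0, n_total]")
  elig_cols <- grep("^eligible\\.", names(df), value = TRUE)
  for (cc in elig_cols)
    if (any(df[[cc]] < 0 | df[[cc]] > df$n_total, na.rm = TRUE))
      stop("eligible counts outside [0, n_total] in ", cc)
  grp <- setdiff(rownames(df), "overall")
  if (length(grp)) {
    for (cc in c("n_total", "incident_cases_6yr", elig_cols)) {
      s <- sum(df[grp, cc])
      if (!is.na(df["overall", cc]) && s != df["overall", cc])
        stop(sprintf("column %s: group rows sum to %d but overall row is %d",
                     cc, s, df["overall", cc]))
    }
  }
  invisible(df)
}

#' Criterion names stored in a group counts table
#' @param counts A `group_counts` object.
#' @return Character vector of criterion names.
#' @export
criteria_names <- function(counts) {
  sub("^eligible\\.", "", grep("^eligible\\.", names(counts), value = TRUE))
}

#' Read a group counts table from long-form CSV
#'
#' Expects columns `group`, `measure` (`n_total`, `incident_cases_6yr`, or
#' `eligible`), `criterion` (empty except for `eligible` rows), `value`,
#' and optionally `pct`. Checks that the group rows sum to the overall row
#' for every column (fatal, naming the offending column) and, when a `pct`
#' column is present, that recomputed row percentages agree with the file
#' to one decimal.
#'
#' @param path Path to the CSV file.
#' @return A `group_counts` object.
#' @export
read_group_counts <- function(path) {
  if (!file.exists(path)) stop("group counts file not found: ", path)
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("group", "measure", "value")
  if (!all(need %in% names(long)))
    stop("group counts file must have columns group, measure, value")
  if (!"criterion" %in% names(long)) long$criterion <- NA_character_
  groups <- unique(long$group)
  groups <- c(setdiff(groups, "overall"), "overall")

  pick <- function(measure, criterion = NA) {
    sel <- long$measure == measure &
      (if (is.na(criterion)) TRUE else long$criterion %in% criterion)
    sub <- long[sel, ]
    v <- sub$value[match(groups, sub$group)]
    as.integer(v)
  }
  crits <- unique(long$criterion[long$measure == "eligible"])
  eligible <- lapply(crits, function(cr) pick("eligible", cr))
  names(eligible) <- crits
  counts <- group_counts(groups, pick("n_total"),
                         pick("incident_cases_6yr"), eligible)

  if ("pct" %in% names(long)) .check_percentages(counts, long)
  counts
}

# one-decimal row-percentage agreement between file and recomputation
.check_percentages <- function(counts, long) {
  grp_n <- counts[long$group, "n_total"]
  overall_n <- counts["overall", "n_total"]
  expected <- ifelse(long$measure == "n_total",
                     long$value / overall_n * 100,
                     long$value / grp_n * 100)
  have <- !is.na(long$pct)
  bad <- have & abs(round(expected, 1) - long$pct) > 0.05 + 1e-9
  if (any(bad))
    stop("row percentages disagree with recomputation: ",
         paste(sprintf("%s/%s (file %.1f, recomputed %.1f)",
                       long$group[bad], long$measure[bad],
                       long$pct[bad], expected[bad]),
               collapse = "; "))
  invisible(TRUE)
}

#' Write a group counts table as long-form CSV
#'
#' Inverse of [read_group_counts()]; recomputed row percentages are
#' included in a `pct` column.
#'
#' @param counts A `group_counts` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_group_counts <- function(counts, path) {
  groups <- rownames(counts)
  rows <- list()
  overall_n <- counts["overall", "n_total"]
  add <- function(measure, criterion, values, denom) {
    rows[[length(rows) + 1L]] <<- data.frame(
      group = groups, measure = measure, criterion = criterion,
      value = values, pct = round(values / denom * 100, 1),
      stringsAsFactors = FALSE)
  }
  add("n_total", NA, counts$n_total, overall_n)
  add("incident_cases_6yr", NA, counts$incident_cases_6yr, counts$n_total)
  for (cr in criteria_names(counts))
    add("eligible", cr, counts[[paste0("eligible.", cr)]], counts$n_total)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Packaged fixture of the cohort characteristics counts
#'
#' Returns the path to the packaged long-form CSV of per-group totals,
#' 6-year incident lung cancer cases, and screening-eligible counts under
#' the USPSTF 2013/2021 rules and the recalibrated risk model at the 1.3%
#' 6-year risk threshold.
#'
#' @return File path (character).
#' @export
cohort_counts_fixture <- function() {
  system.file("extdata", "cohort_group_counts.csv", package = "eiscreen",
              mustWork = TRUE)
}
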