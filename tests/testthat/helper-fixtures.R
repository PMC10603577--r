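# In-code fixtures shared across the suite.

# one participant record with overridable fields
make_record <- function(id = "r1", race_ethnicity = "white", age = 60,
                        sex = "male", education = 3, bmi = 27,
                        copd_emphysema = FALSE,
                        personal_cancer_history = FALSE,
                        family_history_lung_cancer = FALSE,
                        smoking_status = "former", intensity = 20,
                        duration = 30, quit_years = 10,
                        pack_years = NULL,
                        lung_cancer_6yr = FALSE) {
  if (is.null(pack_years)) pack_years <- intensity / 20 * duration
  data.frame(id = id, race_ethnicity = race_ethnicity, age = age,
             sex = sex, education = education, bmi = bmi,
             copd_emphysema = copd_emphysema,
             personal_cancer_history = personal_cancer_history,
             family_history_lung_cancer = family_history_lung_cancer,
             smoking_status = smoking_status, intensity = intensity,
             duration = duration, quit_years = quit_years,
             pack_years = pack_years, lung_cancer_6yr = lung_cancer_6yr,
             stringsAsFactors = FALSE)
}

make_cohort <- function(...) do.call(rbind, list(...))

# minimal valid coefficient set: intercept only (one zero-coefficient term)
toy_model <- function(intercept = -4, races = c(white = 0),
                      name = "toy") {
  coefficient_set(name, intercept,
                  data.frame(variable = "age", transformation = "identity",
                             coefficient = 0),
                  races,
                  merged_race_variant =
                    !all(eiscreen::RACE_LEVELS %in% names(races)))
}

# a two-race cohort with fixed event counts per race (deterministic)
two_race_cohort <- function(n_w = 100, ev_w = 10, n_a = 100, ev_a = 30) {
  w <- make_record(id = paste0("w", seq_len(n_w)), race_ethnicity = "white")
  w <- w[rep(1, n_w), ]; w$id <- paste0("w", seq_len(n_w))
  w$lung_cancer_6yr <- seq_len(n_w) <= ev_w
  a <- make_record(race_ethnicity = "african_american")
  a <- a[rep(1, n_a), ]; a$id <- paste0("a", seq_len(n_a))
  a$lung_cancer_6yr <- seq_len(n_a) <= ev_a
  rbind(w, a)
}

quiet_plco <- function(name = "original") suppressMessages(plco_model(name))

fixture_counts <- function() read_group_counts(cohort_counts_fixture())
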