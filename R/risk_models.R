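# Declarative logistic absolute-risk models: coefficient sets live in
# versioned structured-text files and are evaluated by one generic scorer,
# so the original, merged-race, and cohort-recalibrated model variants are
# just three files consumed by the same code path.

.transform_tokens <- c("identity", "center", "center_scale",
                       "reciprocal_scaled", "indicator")

#' Construct a coefficient set
#'
#' A `coefficient_set` encodes a logistic 6-year absolute-risk model as an
#' intercept, an ordered list of per-term entries (variable,
#' transformation, centering/scaling constants, coefficient), and a map of
#' race/ethnicity coefficients with exactly one reference category at 0.
#'
#' Supported transformations: `identity` (x), `center` (x - center),
#' `center_scale` ((x - center)/scale), `reciprocal_scaled`
#' ((x/scale)^-1 - center; the model's nonlinear smoking-intensity
#' transform, undefined at x <= 0), and `indicator` (1 if x equals
#' `level`).
#'
#' @param model_name Model identifier.
#' @param intercept Intercept on the logit scale.
#' @param terms Data.frame with columns `variable`, `transformation`,
#'   `center`, `scale`, `level`, `coefficient` (missing center/scale
#'   default to 0/1).
#' @param race_coefficients Named numeric vector, one entry per race
#'   category; the reference category has coefficient 0.
#' @param merged_race_variant Logical; `TRUE` for variants that merge
#'   several categories into the reference, in which case the map may omit
#'   the merged categories (they must be mapped with [map_race3l()] before
#'   scoring).
#' @return An object of class `coefficient_set`.
#' @export
coefficient_set <- function(model_name, intercept, terms, race_coefficients,
                            merged_race_variant = FALSE) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  for (cc in c("center", "scale"))
    if (!cc %in% names(terms)) terms[[cc]] <- NA_real_
  if (!"level" %in% names(terms)) terms$level <- NA_character_
  terms$center[is.na(terms$center)] <- 0
  terms$scale[is.na(terms$scale)] <- 1
  need <- c("variable", "transformation", "coefficient")
  if (!all(need %in% names(terms)))
    stop("terms must have variable, transformation, coefficient")
  bad <- setdiff(terms$transformation, .transform_tokens)
  if (length(bad))
    stop("unknown transformation token: ", paste(bad, collapse = ", "))
  bad <- setdiff(terms$variable, COHORT_COLUMNS)
  if (length(bad))
    stop("term variable not a participant field: ",
         paste(bad, collapse = ", "))
  if (!all(is.finite(terms$center)) || !all(is.finite(terms$scale)) ||
      !all(is.finite(terms$coefficient)) || !is.finite(intercept))
    stop("non-finite model parameters")
  rc <- unlist(race_coefficients)
  if (sum(rc == 0) != 1)
    stop("ambiguous reference: exactly one race must have coefficient 0")
  if (!merged_race_variant && !all(RACE_LEVELS %in% names(rc)))
    stop("race_coefficients missing categories: ",
         paste(setdiff(RACE_LEVELS, names(rc)), collapse = ", "))
  structure(list(model_name = model_name, intercept = intercept,
                 terms = terms, race_coefficients = rc,
                 merged_race_variant = isTRUE(merged_race_variant)),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<coefficient_set> %s: intercept %.6f, %d terms, races: %s\n",
              x$model_name, x$intercept, nrow(x$terms),
              paste(names(x$race_coefficients), collapse = ", ")))
  invisible(x)
}

#' Load a coefficient set from a structured-text file
#'
#' Reads a YAML coefficient file (schema version tag required), validates
#' it, and logs the MD5 checksum of the file.
#'
#' @param path Path to the YAML file.
#' @return A `coefficient_set`.
#' @export
load_coefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version))
    stop("coefficient file lacks a schema_version tag")
  terms <- do.call(rbind, lapply(doc$terms, function(t)
    data.frame(variable = t$variable, transformation = t$transformation,
               center = if (is.null(t$center)) NA_real_ else t$center,
               scale = if (is.null(t$scale)) NA_real_ else t$scale,
               level = if (is.null(t$level)) NA_character_ else t$level,
               coefficient = t$coefficient, stringsAsFactors = FALSE)))
  model <- coefficient_set(doc$model_name, doc$intercept, terms,
                           doc$race_coefficients,
                           isTRUE(doc$merged_race_variant))
  message(sprintf("loaded %s (md5 %s)", doc$model_name,
                  unname(tools::md5sum(path))))
  model
}

#' Write a coefficient set to a structured-text file
#'
#' @param model A `coefficient_set`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(model, path) {
  terms <- lapply(seq_len(nrow(model$terms)), function(i) {
    t <- model$terms[i, ]
    out <- list(variable = t$variable, transformation = t$transformation)
    if (t$center != 0) out$center <- t$center
    if (t$scale != 1) out$scale <- t$scale
    if (!is.na(t$level)) out$level <- t$level
    out$coefficient <- t$coefficient
    out
  })
  doc <- list(schema_version = 1L, model_name = model$model_name,
              intercept = model$intercept, terms = terms,
              race_coefficients = as.list(model$race_coefficients))
  if (model$merged_race_variant) doc$merged_race_variant <- TRUE
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Packaged PLCOm2012 coefficient sets
#'
#' Loads one of the packaged coefficient files: `"original"` (the published
#' 11-predictor model with the five-category race map) or `"race3l"` (the
#' merged-race variant with Asian, Hispanic, and Native Hawaiian/Other
#' Pacific Islander collapsed into the White reference; a derived file, see
#' the file header).
#'
#' @param name `"original"` or `"race3l"`.
#' @return A `coefficient_set`.
#' @export
plco_model <- function(name = c("original", "race3l")) {
  name <- match.arg(name)
  load_coefficients(system.file(
    "extdata", paste0("plcom2012_", name, ".yaml"),
    package = "eiscreen", mustWork = TRUE))
}

.term_value <- function(records, t) {
  x <- records[[t$variable]]
  switch(t$transformation,
         identity = as.numeric(x),
         center = as.numeric(x) - t$center,
         center_scale = (as.numeric(x) - t$center) / t$scale,
         reciprocal_scaled = {
           if (any(as.numeric(x) <= 0))
             stop("non-positive ", t$variable,
                  " under reciprocal_scaled transform")
           (as.numeric(x) / t$scale)^(-1) - t$center
         },
         indicator = as.numeric(as.character(x) == t$level))
}

#' Linear predictor of a coefficient set
#'
#' Intercept plus the sum of coefficient times transformed covariate plus
#' the race/ethnicity coefficient. With `include_race = FALSE` the race
#' term is omitted, which is the fixed offset used when re-estimating the
#' race-related parameters.
#'
#' @param records Data.frame of participant records.
#' @param model A `coefficient_set`.
#' @param include_race Include the race coefficient? Default `TRUE`.
#' @return Numeric vector of linear predictors (logit scale).
#' @export
linear_predictor <- function(records, model, include_race = TRUE) {
  lp <- rep(model$intercept, nrow(records))
  for (i in seq_len(nrow(model$terms))) {
    t <- model$terms[i, ]
    lp <- lp + t$coefficient * .term_value(records, t)
  }
  if (include_race) {
    rc <- model$race_coefficients[as.character(records$race_ethnicity)]
    if (any(is.na(rc)))
      stop("record race not in model's race map: ",
           paste(unique(records$race_ethnicity[is.na(rc)]), collapse = ", "),
           if (model$merged_race_variant)
             " (map records with map_race3l() first)" else "")
    lp <- lp + unname(rc)
  }
  lp
}

#' Compute 6-year absolute risk scores
#'
#' Evaluates a coefficient set on participant records: the linear
#' predictor on the logit scale and the absolute risk
#' `1 / (1 + exp(-lp))`. Deterministic; vectorized over records.
#'
#' @param records Data.frame of participant records.
#' @param model A `coefficient_set`.
#' @return Data.frame with columns `id`, `linear_predictor`, `risk`.
#' @export
compute_risk <- function(records, model) {
  lp <- linear_predictor(records, model)
  data.frame(id = records$id, linear_predictor = lp,
             risk = stats::plogis(lp), stringsAsFactors = FALSE)
}

#' Merge race categories for the 3-level-race model variant
#'
#' Maps Japanese American, Latino, and Native Hawaiian/Other Pacific
#' Islander to the White reference category; African American and White
#' are unchanged. Pure function of the records.
#'
#' @param records Data.frame of participant records.
#' @return The records with `race_ethnicity` collapsed to
#'   `{african_american, white}`.
#' @export
map_race3l <- function(records) {
  merged <- c("japanese_american", "latino", "nhpi")
  bad <- setdiff(unique(as.character(records$race_ethnicity)), RACE_LEVELS)
  if (length(bad)) stop("unknown race categories: ",
                        paste(bad, collapse = ", "))
  records$race_ethnicity <- ifelse(
    records$race_ethnicity %in% merged, "white",
    as.character(records$race_ethnicity))
  records
}
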