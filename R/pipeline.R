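# End-to-end orchestration: simulate (or read) a cohort, score it,
# recalibrate the race parameters, cross-validate, assess eligibility,
# run the E-I disparity analysis and screening-performance metrics, and
# write a consolidated report plus a run manifest. All randomness flows
# from one root seed expanded per stage.

#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()].
#' Override fields by passing a modified copy (or a YAML file whose
#' entries replace defaults).
#'
#' @param seed Root seed.
#' @param n Synthetic cohort size (when `cohort_path` is `NULL`).
#' @param cohort_path Optional path to a cohort CSV; when given the
#'   simulate stage is skipped.
#' @param counts_path Optional path to a group counts CSV; when given,
#'   the pipeline runs the disparity stage directly on those counts and
#'   skips the individual-level stages.
#' @param stages Character vector of stages to run, in order.
#' @return Configuration list.
#' @export
pipeline_config <- function(seed = 1L, n = 20000L, cohort_path = NULL,
                            counts_path = NULL,
                            stages = c("simulate", "score", "recalibrate",
                                       "validate", "eligibility",
                                       "disparity", "report")) {
  list(seed = as.integer(seed), n = as.integer(n),
       cohort_path = cohort_path, counts_path = counts_path,
       stages = stages,
       analysis = analysis_config(rng_seed = seed),
       boot_reps = 500L,
       base_model = "original")
}

.stage_seed <- function(root, k) (as.integer(root) * 113L + k * 7919L) %%
  .Machine$integer.max

.md_table <- function(df, digits = 3) {
  fmt <- function(x) if (is.numeric(x)) signif(x, digits) else x
  df[] <- lapply(df, fmt)
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, body)
}

#' Run the full screening-disparity pipeline
#'
#' Executes the requested stages in order and writes every stage output
#' (CSV), a markdown summary report, and a JSON run manifest under one
#' output directory. Deterministic outputs are byte-identical across
#' reruns with the same configuration and seed.
#'
#' @param config A [pipeline_config()] list, or a path to a YAML file
#'   whose entries override the defaults.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(
      pipeline_config(seed = if (is.null(user$seed)) 1L else user$seed),
      user)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  acfg <- config$analysis
  stages <- config$stages

  counts <- NULL
  if (!is.null(config$counts_path)) {
    counts <- read_group_counts(config$counts_path)
    stages <- intersect(stages, c("disparity", "report"))
  }

  if (is.null(counts)) {
    base <- plco_model(config$base_model)
    if (!is.null(config$cohort_path)) {
      cohort <- read_cohort(config$cohort_path)
    } else {
      spec <- synthetic_spec(config$n,
                             seed = .stage_seed(config$seed, 1L),
                             true_model = base)
      cohort <- generate_cohort(spec)
    }
    if ("simulate" %in% stages || !is.null(config$cohort_path))
      write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    res$cohort <- cohort

    recal <- fit_race_recalibration(cohort, base)
    res$recalibration <- recal
    if ("recalibrate" %in% stages) {
      write_coefficients(recal$updated_model,
                         file.path(out_dir, "model_update.yaml"))
      utils::write.csv(recal$estimates,
                       file.path(out_dir, "recalibration_estimates.csv"),
                       row.names = FALSE)
    }

    scores <- compute_risk(cohort, recal$updated_model)
    res$scores <- scores
    if ("score" %in% stages)
      utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                       row.names = FALSE)

    if ("validate" %in% stages) {
      oof <- crossfit_predictions(cohort, base, folds = acfg$cv_folds,
                                  seed = .stage_seed(config$seed, 2L))
      vrep <- validation_report(oof$risk, cohort,
                                boot_reps = config$boot_reps,
                                seed = .stage_seed(config$seed, 3L))
      res$validation <- vrep
      utils::write.csv(vrep, file.path(out_dir, "validation.csv"),
                       row.names = FALSE)
      dec <- attr(vrep, "deciles")
      dec_df <- do.call(rbind, lapply(names(dec), function(g)
        cbind(group = g, dec[[g]])))
      utils::write.csv(dec_df, file.path(out_dir, "calibration_deciles.csv"),
                       row.names = FALSE)
    }

    # rule criteria plus the eligibility-matched risk threshold
    crit <- list(uspstf_2013(), uspstf_2021())
    e21 <- is_eligible(cohort, uspstf_2021())
    thr <- match_threshold(scores, cohort$age, sum(e21),
                           age_window = acfg$age_window)
    crit <- c(crit, list(risk_criterion(thr, name = "plco_update",
                                        age_window = acfg$age_window,
                                        model_name =
                                          recal$updated_model$model_name)))
    res$matched_threshold <- thr
    counts <- eligibility_summary(cohort, crit, scores)
    if ("eligibility" %in% stages)
      write_group_counts(counts, file.path(out_dir, "group_counts.csv"))
    if ("disparity" %in% stages) {
      perf <- performance_table(cohort, crit, scores)
      res$performance <- perf
      utils::write.csv(perf, file.path(out_dir, "performance.csv"),
                       row.names = FALSE)
    }
  }
  res$counts <- counts

  if ("disparity" %in% stages) {
    ei <- disparity_table(counts, acfg)
    res$disparity <- ei
    utils::write.csv(ei, file.path(out_dir, "ei_results.csv"),
                     row.names = FALSE)
  }

  if ("report" %in% stages) {
    lines <- c("# Screening eligibility and disparity report", "",
               sprintf("Seed: %d", config$seed), "")
    if (!is.null(res$disparity)) {
      lines <- c(lines, "## E-I ratio disparity", "",
                 .md_table(res$disparity), "")
    }
    if (!is.null(res$performance)) {
      lines <- c(lines, "## Screening performance", "",
                 .md_table(res$performance), "")
    }
    if (!is.null(res$validation)) {
      lines <- c(lines, "## Model validation (out-of-fold)", "",
                 .md_table(res$validation), "")
    }
    writeLines(lines, file.path(out_dir, "report.md"))
  }

  manifest <- list(
    seed = config$seed, stages = stages,
    n_records = if (!is.null(res$cohort)) nrow(res$cohort) else NA,
    matched_threshold = res$matched_threshold,
    packaged_models = as.list(tools::md5sum(c(
      system.file("extdata", "plcom2012_original.yaml",
                  package = "eiscreen"),
      system.file("extdata", "plcom2012_race3l.yaml",
                  package = "eiscreen")))),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
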