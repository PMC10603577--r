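# Race-stratified predictive-performance metrics: rank-statistic AUC with
# a stratified-bootstrap CI, decile calibration (table + OLS slope), and
# the Brier score.

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a randomly chosen
#' event outranks a randomly chosen non-event, with ties counted one half.
#'
#' @param scores Numeric predicted risks.
#' @param outcomes Logical (or 0/1) outcomes.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("undefined AUC: need at least one event and one non-event")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile interval from a stratified bootstrap (events and non-events
#' resampled separately), seeded for reproducibility.
#'
#' @param scores Numeric predicted risks.
#' @param outcomes Logical outcomes.
#' @param reps Bootstrap replicates. Default 2000.
#' @param conf Confidence level. Default 0.95.
#' @param seed RNG seed.
#' @return Named numeric `c(lo, hi)`.
#' @export
auc_ci <- function(scores, outcomes, reps = 2000L, conf = 0.95, seed = 1L) {
  y <- as.logical(outcomes)
  i1 <- which(y); i0 <- which(!y)
  set.seed(seed)
  stat <- vapply(seq_len(reps), function(r) {
    b <- c(sample(i1, length(i1), replace = TRUE),
           sample(i0, length(i0), replace = TRUE))
    auc(scores[b], y[b])
  }, numeric(1))
  a <- (1 - conf) / 2
  q <- stats::quantile(stat, c(a, 1 - a), names = FALSE, type = 1)
  c(lo = q[1], hi = q[2])
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; lower is better.
#'
#' @param scores Numeric predicted risks.
#' @param outcomes Logical outcomes.
#' @return Brier score in [0, 1].
#' @export
brier <- function(scores, outcomes) {
  if (!length(scores)) stop("empty score vector")
  mean((scores - as.numeric(as.logical(outcomes)))^2)
}

#' Decile calibration table and slope
#'
#' Partitions records into `bins` groups by predicted-risk quantiles
#' (inverse-ECDF convention, realized as stable-order rank splitting so
#' tied scores are assigned by record order) and regresses the observed
#' event proportion on the mean predicted risk across bins by ordinary
#' least squares. A slope of 1 indicates perfect calibration; a slope
#' above 1 indicates risk underestimation.
#'
#' @param scores Numeric predicted risks.
#' @param outcomes Logical outcomes.
#' @param bins Number of quantile groups. Default 10.
#' @return List with `table` (data.frame `bin`, `n`, `mean_predicted`,
#'   `observed`) and `slope`.
#' @export
calibration <- function(scores, outcomes, bins = 10L) {
  n <- length(scores)
  if (n < bins) stop("need at least as many records as bins")
  if (length(unique(scores)) < bins)
    warning("fewer distinct scores than bins; some bins share scores")
  y <- as.numeric(as.logical(outcomes))
  ord <- order(scores, seq_len(n))           # stable tie-break
  bin <- integer(n)
  bin[ord] <- floor(bins * (seq_len(n) - 1) / n) + 1L
  tab <- data.frame(
    bin = seq_len(bins),
    n = as.integer(tabulate(bin, bins)),
    mean_predicted = vapply(seq_len(bins), function(b)
      mean(scores[bin == b]), numeric(1)),
    observed = vapply(seq_len(bins), function(b)
      mean(y[bin == b]), numeric(1)))
  slope <- unname(stats::coef(stats::lm(observed ~ mean_predicted,
                                        data = tab))[2])
  list(table = tab, slope = slope)
}

#' Race-stratified validation report
#'
#' Computes, per group and overall, the AUC with bootstrap CI, the Brier
#' score, and the decile calibration slope for a vector of predicted risks
#' (typically out-of-fold predictions from [crossfit_predictions()]).
#'
#' @param scores Numeric predicted risks aligned with `cohort`.
#' @param cohort Data.frame of participant records.
#' @param bins Calibration bins. Default 10.
#' @param boot_reps Bootstrap replicates for the AUC CI. Default 2000.
#' @param seed RNG seed for the bootstrap.
#' @return Data.frame, one row per group plus overall: `group`, `n`,
#'   `events`, `auc`, `auc_lo`, `auc_hi`, `brier`, `calibration_slope`;
#'   attribute `deciles` is the named list of per-group calibration
#'   tables.
#' @export
validation_report <- function(scores, cohort, bins = 10L,
                              boot_reps = 2000L, seed = 1L) {
  risk <- if (is.data.frame(scores)) scores$risk else as.numeric(scores)
  y <- as.logical(cohort$lung_cancer_6yr)
  groups <- c(intersect(RACE_LEVELS, unique(cohort$race_ethnicity)),
              "overall")
  deciles <- list()
  rows <- lapply(groups, function(g) {
    sel <- if (g == "overall") rep(TRUE, length(y))
           else cohort$race_ethnicity == g
    s <- risk[sel]; o <- y[sel]
    ci <- auc_ci(s, o, reps = boot_reps, seed = seed)
    cal <- calibration(s, o, bins = bins)
    deciles[[g]] <<- cal$table
    data.frame(group = g, n = sum(sel), events = sum(o),
               auc = auc(s, o), auc_lo = ci[["lo"]], auc_hi = ci[["hi"]],
               brier = brier(s, o), calibration_slope = cal$slope,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "deciles") <- deciles
  out
}
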