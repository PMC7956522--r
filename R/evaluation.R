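# Agreement evaluation of BP estimates: signed/absolute/root-mean-square
# errors, cumulative-percentage table with BHS grading, the AAMI verdict,
# and (variant) Bland-Altman statistics.

#' Error metrics between truth and prediction
#'
#' Mean error `mean(y - yhat)` (signed), mean absolute error and
#' root-mean-square error, all in mmHg, plus the sample standard deviation
#' of the errors (used by the strict AAMI mode).
#'
#' @param truth,pred Equal-length numeric vectors, mmHg.
#' @return Object of class `bp_error_metrics`: `merr`, `maerr`, `rmserr`,
#'   `sd_err`, `n`.
#' @export
error_metrics <- function(truth, pred) {
  if (!length(truth) || length(truth) != length(pred))
    stop("`truth` and `pred` must be non-empty and of equal length")
  e <- truth - pred
  structure(list(merr = mean(e), maerr = mean(abs(e)),
                 rmserr = sqrt(mean(e^2)),
                 sd_err = if (length(e) > 1) stats::sd(e) else 0,
                 n = length(e)),
            class = "bp_error_metrics")
}

#' Cumulative percentages of absolute errors
#'
#' Percentage of absolute errors within (inclusive) 5, 10 and 15 mmHg.
#'
#' @param truth,pred Equal-length numeric vectors, mmHg.
#' @return Named numeric `c(cp5, cp10, cp15)` in percent.
#' @export
cumulative_percentages <- function(truth, pred) {
  if (!length(truth) || length(truth) != length(pred))
    stop("`truth` and `pred` must be non-empty and of equal length")
  ae <- abs(truth - pred)
  c(cp5 = 100 * mean(ae <= 5), cp10 = 100 * mean(ae <= 10),
    cp15 = 100 * mean(ae <= 15))
}

.BHS_THRESHOLDS <- rbind(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))

#' BHS grade from a cumulative-percentage table
#'
#' Grade A requires cp5 >= 60, cp10 >= 85, cp15 >= 95; B requires
#' 50/75/90; C requires 40/65/85 (all inclusive). The best satisfied grade
#' is returned, otherwise `"fail"`.
#'
#' @param cp Numeric `c(cp5, cp10, cp15)`.
#' @return `"A"`, `"B"`, `"C"` or `"fail"`.
#' @examples
#' bhs_grade(c(71.52, 89.56, 95.03)) # "A"
#' @export
bhs_grade <- function(cp) {
  for (g in rownames(.BHS_THRESHOLDS))
    if (all(cp >= .BHS_THRESHOLDS[g, ])) return(g)
  "fail"
}

#' AAMI verdict
#'
#' In the default `"maerr"` mode the device passes when `|MErr| <= 5` mmHg
#' and `MAErr <= 8` mmHg. The `"strict"` mode applies the standard's
#' mean +/- SD form instead: `|MErr| <= 5` and the error standard
#' deviation `<= 8`.
#'
#' @param metrics A `bp_error_metrics`.
#' @param mode `"maerr"` (MErr/MAErr bounds, default) or `"strict"`
#'   (MErr/SD bounds).
#' @return `"pass"` or `"fail"`.
#' @export
aami_check <- function(metrics, mode = c("maerr", "strict")) {
  mode <- match.arg(mode)
  second <- if (mode == "maerr") metrics$maerr else metrics$sd_err
  if (abs(metrics$merr) <= 5 && second <= 8) "pass" else "fail"
}

#' Bland-Altman agreement statistics
#'
#' Differences are estimated minus ground truth; limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) standard deviation. The
#' per-point export plots the difference against the pair mean.
#'
#' @param truth,pred Equal-length numeric vectors of length >= 2, mmHg.
#' @return List with `mean_diff`, `sd_diff`, `lower_loa`, `upper_loa` and
#'   an `export` data frame of `(x, diff)` rows.
#' @export
bland_altman <- function(truth, pred) {
  if (length(truth) < 2L || length(truth) != length(pred))
    stop("`truth` and `pred` must be of equal length >= 2")
  d <- pred - truth
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       lower_loa = m - 1.96 * s, upper_loa = m + 1.96 * s,
       export = data.frame(x = (truth + pred) / 2, diff = d))
}

#' Variant Bland-Altman export
#'
#' Identical statistics to [bland_altman()], but the export's x-axis is the
#' ground-truth value itself — useful when many references cluster around a
#' fixed pressure and the conventional mean-axis smears them.
#'
#' @param truth,pred Equal-length numeric vectors, mmHg.
#' @return As [bland_altman()], with `export$x = truth`.
#' @export
variant_bland_altman <- function(truth, pred) {
  ba <- bland_altman(truth, pred)
  ba$export <- data.frame(x = truth, diff = pred - truth)
  ba
}

#' Full evaluation report for multitask predictions
#'
#' @param truth,pred `n x k` matrices (columns = tasks, e.g. sbp/dbp/map),
#'   mmHg.
#' @param tasks Task names; defaults to the truth column names.
#' @return Object of class `bp_eval_report`: per task the error metrics,
#'   CP table, BHS grade, AAMI verdict, and both Bland-Altman variants.
#' @export
evaluate_bp <- function(truth, pred, tasks = colnames(truth)) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (is.null(tasks)) tasks <- paste0("task", seq_len(ncol(truth)))
  per_task <- stats::setNames(lapply(seq_along(tasks), function(k) {
    m <- error_metrics(truth[, k], pred[, k])
    cp <- cumulative_percentages(truth[, k], pred[, k])
    list(metrics = m, cp = cp, bhs = bhs_grade(cp), aami = aami_check(m),
         bland_altman = bland_altman(truth[, k], pred[, k]),
         variant_bland_altman = variant_bland_altman(truth[, k], pred[, k]))
  }), tasks)
  structure(list(tasks = per_task, n = nrow(truth)), class = "bp_eval_report")
}

#' @export
print.bp_eval_report <- function(x, ...) {
  cat(sprintf("BP evaluation over %d segments\n", x$n))
  for (nm in names(x$tasks)) {
    tk <- x$tasks[[nm]]
    cat(sprintf(
      "  %-3s MErr % 6.2f  MAErr %5.2f  RMSErr %5.2f mmHg | CP5/10/15 %5.1f/%5.1f/%5.1f%% | BHS %-4s AAMI %s\n",
      nm, tk$metrics$merr, tk$metrics$maerr, tk$metrics$rmserr,
      tk$cp[1], tk$cp[2], tk$cp[3], tk$bhs, tk$aami))
  }
  invisible(x)
}

# JSON-serializable view of a report (stable field order and digits so that
# identical runs write identical files)
.report_as_list <- function(report) {
  lapply(report$tasks, function(tk) list(
    merr = tk$metrics$merr, maerr = tk$metrics$maerr,
    rmserr = tk$metrics$rmserr, sd_err = tk$metrics$sd_err,
    n = tk$metrics$n,
    cp5 = unname(tk$cp[1]), cp10 = unname(tk$cp[2]), cp15 = unname(tk$cp[3]),
    bhs_grade = tk$bhs, aami = tk$aami,
    bland_altman = list(mean_diff = tk$bland_altman$mean_diff,
                        sd_diff = tk$bland_altman$sd_diff,
                        lower_loa = tk$bland_altman$lower_loa,
                        upper_loa = tk$bland_altman$upper_loa)))
}

#' Write an evaluation report and its plot exports
#'
#' Writes `report.json` plus per-task CSV exports of both Bland-Altman
#' variants into `dir`.
#'
#' @param report A `bp_eval_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.report_as_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10)
  for (nm in names(report$tasks)) {
    utils::write.csv(report$tasks[[nm]]$bland_altman$export,
                     file.path(dir, sprintf("bland_altman_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(report$tasks[[nm]]$variant_bland_altman$export,
                     file.path(dir, sprintf("variant_bland_altman_%s.csv", nm)),
                     row.names = FALSE)
  }
  invisible(dir)
}
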