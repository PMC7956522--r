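# Ground-truth extraction from ABP with a skewness quality gate. A clean
# arterial pulse spends most of each beat near diastole with a brief
# systolic peak, so its amplitude distribution is right-skewed; artifact
# (clots, flushes, transducer failure) typically produces negative skew.

#' Sample skewness (moment coefficient g1)
#'
#' Fisher-Pearson `g1 = m3 / m2^(3/2)` with central moments over the window
#' (population convention, the usual signal-quality form). Windows with
#' fewer than 3 samples or (near-)zero variance return `-Inf`, a sentinel
#' that always fails the quality gate.
#'
#' @param window Numeric series.
#' @return Dimensionless skewness, or `-Inf` for degenerate windows.
#' @examples
#' sample_skewness(c(1, 2, 3, 2, 1)) # 0
#' @export
sample_skewness <- function(window) {
  if (length(window) < 3L) return(-Inf)
  if (stats::var(window) < 1e-24) return(-Inf)
  as.numeric(e1071::skewness(window, type = 1))
}

#' Quality-gate a 10-s ABP window by per-second skewness
#'
#' Computes skewness on consecutive non-overlapping 1-s sub-windows and
#' fails the whole segment iff any sub-window skewness is below 0 (exactly
#' zero passes). The paired ECG segment inherits the verdict.
#'
#' @param abp_window ABP series spanning an integer number of seconds.
#' @param fs Sampling rate, Hz.
#' @return `TRUE` if every 1-s sub-window has skewness >= 0.
#' @export
qc_abp <- function(abp_window, fs) {
  n_sec <- length(abp_window) / fs
  if (abs(n_sec - round(n_sec)) > 1e-9)
    stop("`abp_window` must span an integer number of seconds")
  n_sec <- round(n_sec)
  for (s in seq_len(n_sec)) {
    idx <- ((s - 1L) * fs + 1L):(s * fs)
    if (sample_skewness(abp_window[idx]) < 0) return(FALSE)
  }
  TRUE
}

#' Extract SBP/DBP/MAP targets from an ABP window
#'
#' Systolic pressure is the window maximum, diastolic the minimum, and mean
#' arterial pressure follows the standard identity
#' `MAP = (SBP + 2 * DBP) / 3`.
#'
#' @param abp_window Non-empty ABP series in mmHg.
#' @return Object of class `bp_targets`: list `sbp`, `dbp`, `map` (mmHg).
#' @examples
#' extract_targets(c(60, 120, 60))$map # 80
#' @export
extract_targets <- function(abp_window) {
  if (!length(abp_window)) stop("`abp_window` must be non-empty")
  sbp <- max(abp_window); dbp <- min(abp_window)
  structure(list(sbp = sbp, dbp = dbp, map = (sbp + 2 * dbp) / 3),
            class = "bp_targets")
}

#' Build a labeled segment dataset from a synthetic cohort
#'
#' Preprocesses every record, quality-gates each ABP window, and extracts
#' SBP/DBP/MAP targets for the segments that pass. Targets of discarded
#' segments are `NA`.
#'
#' @param dataset A `bp_dataset` from [make_dataset()].
#' @param spec A [wavelet_spec()].
#' @param fs_out ECG rate after downsampling, Hz.
#' @param duration_s Segment length, seconds.
#' @return Object of class `labeled_bp_data`: `x` (n x 1000 normalized ECG
#'   matrix), `y` (n x 3 matrix, columns sbp/dbp/map, mmHg, `NA` where QC
#'   failed), logical `qc`, and `meta` (record_id, split, start_index).
#' @export
build_labeled_dataset <- function(dataset, spec = wavelet_spec(),
                                  fs_out = 100, duration_s = 10) {
  if (!inherits(dataset, "bp_dataset")) stop("`dataset` must be a bp_dataset")
  split_of <- stats::setNames(dataset$manifest$split, dataset$manifest$record_id)
  rows_x <- list(); rows_y <- list(); qc <- logical(0); meta <- list()
  for (rec in dataset$records) {
    segs <- preprocess_record(rec, spec, fs_out, duration_s)
    for (sg in segs) {
      ok <- qc_abp(sg$abp, sg$fs_abp)
      tgt <- if (ok) extract_targets(sg$abp) else list(sbp = NA_real_, dbp = NA_real_, map = NA_real_)
      rows_x[[length(rows_x) + 1L]] <- sg$ecg
      rows_y[[length(rows_y) + 1L]] <- c(tgt$sbp, tgt$dbp, tgt$map)
      qc <- c(qc, ok)
      meta[[length(meta) + 1L]] <- data.frame(
        record_id = sg$source_record,
        split = unname(split_of[as.character(sg$source_record)]),
        start_index = sg$start_index)
    }
  }
  if (!length(rows_x))
    stop("no segments could be formed (records shorter than one window?)")
  x <- do.call(rbind, rows_x)
  y <- do.call(rbind, rows_y)
  colnames(y) <- c("sbp", "dbp", "map")
  structure(list(x = x, y = y, qc = qc, meta = do.call(rbind, meta)),
            class = "labeled_bp_data")
}

#' Write / read a labeled dataset as plain CSV
#'
#' One row per segment: metadata and targets first, then the 1000 ECG
#' sample columns.
#'
#' @param data A `labeled_bp_data`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labeled_data <- function(data, path) {
  df <- cbind(data$meta,
              qc = data$qc,
              as.data.frame(data$y),
              as.data.frame(data$x))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labeled_data
#' @export
read_labeled_data <- function(path) {
  df <- utils::read.csv(path)
  meta_cols <- c("record_id", "split", "start_index")
  y <- as.matrix(df[, c("sbp", "dbp", "map")])
  x_cols <- setdiff(colnames(df), c(meta_cols, "qc", "sbp", "dbp", "map"))
  structure(list(x = unname(as.matrix(df[, x_cols])), y = y,
                 qc = as.logical(df$qc), meta = df[, meta_cols]),
            class = "labeled_bp_data")
}
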