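# Synthetic paired ECG/ABP generator. Every downstream stage (denoising,
# quality control, labeling, training, evaluation) is exercised on records
# whose ground-truth blood pressure is known by construction.

# Stable per-stream seed derivation so that record k is reproducible on its
# own, independent of how many records were generated before it.
.derive_seed <- function(master, stream) {
  s <- (as.numeric(master) %% 2147483647) * 48271 + as.numeric(stream) * 40503 + 97
  as.integer(s %% 2147483629) + 1L
}

#' Simulation configuration for paired ECG/ABP records
#'
#' Defines the study conditions for the synthetic cohort: one record is one
#' subject-segment with a record-level systolic/diastolic pressure drawn from
#' the population distribution, a quasi-periodic ABP pulse train oscillating
#' between those pressures, and an ECG spike train whose R-wave amplitude and
#' heart rate encode the pressures linearly with strength
#' `coupling_strength`. Baseline wander (a slow sinusoid), high-frequency
#' noise (> 45 Hz) and negatively skewed ABP artifacts are injectable.
#'
#' @param n_records Number of records.
#' @param duration_s Seconds per record.
#' @param fs Sampling rate in Hz for both signals.
#' @param sbp_mean,sbp_sd Population systolic pressure, mmHg.
#' @param dbp_mean,dbp_sd Population diastolic pressure, mmHg.
#' @param heart_rate_range Interval of resting heart rates, beats/min.
#' @param wander_amplitude Baseline-wander amplitude as a fraction of the
#'   clean ECG range.
#' @param wander_freq_hz Wander frequency, must be below 0.5 Hz.
#' @param hf_noise_sd Standard deviation of the high-frequency ECG noise, in
#'   ECG amplitude units.
#' @param artifact_rate Probability that each 1-s ABP window is replaced by a
#'   negative-skew artifact.
#' @param coupling_strength In `[0, 1]`: 0 means the ECG carries no pressure
#'   information, 1 means R-amplitude and heart rate are deterministic linear
#'   functions of (SBP, DBP).
#' @param beat_jitter_sd Per-beat Gaussian jitter of SBP/DBP around the
#'   record-level values, mmHg (0 disables).
#' @param seed Master seed; record `k` uses a stream derived from
#'   `(seed, k)`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_records = 100L, duration_s = 60, fs = 125,
                       sbp_mean = 120, sbp_sd = 10,
                       dbp_mean = 60, dbp_sd = 7,
                       heart_rate_range = c(60, 100),
                       wander_amplitude = 0.1, wander_freq_hz = 0.25,
                       hf_noise_sd = 0.05, artifact_rate = 0,
                       coupling_strength = 1, beat_jitter_sd = 1,
                       seed = 1L) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (fs <= 0) stop("`fs` must be positive")
  if (dbp_mean >= sbp_mean) stop("`dbp_mean` must be below `sbp_mean`")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("`artifact_rate` must lie in [0, 1]")
  if (wander_freq_hz >= 0.5) stop("`wander_freq_hz` must be below 0.5 Hz")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("`coupling_strength` must lie in [0, 1]")
  if (length(heart_rate_range) != 2L || diff(heart_rate_range) < 0)
    stop("`heart_rate_range` must be an increasing interval")
  structure(
    list(n_records = as.integer(n_records), duration_s = duration_s, fs = fs,
         sbp_mean = sbp_mean, sbp_sd = sbp_sd,
         dbp_mean = dbp_mean, dbp_sd = dbp_sd,
         heart_rate_range = heart_rate_range,
         wander_amplitude = wander_amplitude,
         wander_freq_hz = wander_freq_hz,
         hf_noise_sd = hf_noise_sd, artifact_rate = artifact_rate,
         coupling_strength = coupling_strength,
         beat_jitter_sd = beat_jitter_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Linear code from pressure to ECG morphology: R-wave amplitude tracks SBP
# (ejection intensity), heart rate tracks DBP.
.amp_map <- function(sbp) 0.8 + 0.01 * (sbp - 100)
.hr_map <- function(dbp) 75 + 0.5 * (dbp - 60)

# One ABP beat sampled on the grid: raised-cosine upstroke from DBP to SBP
# (the peak lands exactly on a sample) followed by a normalized exponential
# decay that reaches exactly DBP at the last sample. The long lower tail
# gives the positive skewness characteristic of arterial pulses.
.abp_beat <- function(sbp, dbp, n_samples, fs) {
  n_up <- max(3L, round(0.12 * fs))
  n_up <- min(n_up, n_samples - 2L)
  up <- dbp + (sbp - dbp) * (1 - cos(pi * seq(0, 1, length.out = n_up + 1L))) / 2
  n_dec <- n_samples - n_up - 1L
  tau <- 0.18 * fs
  tt <- seq_len(n_dec)
  g <- (exp(-tt / tau) - exp(-n_dec / tau)) / (1 - exp(-n_dec / tau))
  c(up, dbp + (sbp - dbp) * g)
}

# left-skewed 1-s disturbance: the mirror image of a clean pulse train,
# whose sample skewness is exactly the negative of the (positive) pulse skew
.artifact_window <- function(sbp, dbp, fs) {
  n <- as.integer(fs)
  hr <- 75
  n_beat <- max(5L, round(fs * 60 / hr))
  beats <- ceiling(n / n_beat) + 1L
  pulse <- rep(.abp_beat(sbp, dbp, n_beat, fs), beats)[seq_len(n)]
  flipped <- (sbp + dbp) - pulse
  flipped + stats::rnorm(n, sd = 0.25)
}

#' Generate one synthetic ECG/ABP record
#'
#' Deterministic given `(cfg$seed, record_index)`. The ABP is a pulse train
#' whose per-beat maxima and minima equal the drawn per-beat SBP and DBP
#' exactly; the ECG is a train of Gaussian R-wave spikes whose amplitude and
#' spacing encode (SBP, DBP) with strength `coupling_strength`, plus a
#' sub-0.5 Hz sinusoidal baseline wander and high-pass (> 45 Hz) noise.
#'
#' @param cfg A [sim_config()].
#' @param record_index Zero-based record index, `< cfg$n_records`.
#' @return An object of class `signal_record`: list with `ecg`, `abp`, `fs`,
#'   per-beat `truth_sbp`/`truth_dbp`, beat onset indices, record-level
#'   `sbp`/`dbp`/`hr`, and the indices of artifact-corrupted 1-s windows.
#' @examples
#' rec <- generate_record(sim_config(duration_s = 10), 0)
#' range(rec$abp)
#' @export
generate_record <- function(cfg, record_index = 0L) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config")
  if (record_index < 0L || record_index >= cfg$n_records)
    stop("`record_index` must lie in [0, n_records)")
  withr::with_seed(.derive_seed(cfg$seed, record_index), {
    n <- round(cfg$duration_s * cfg$fs)
    sbp <- stats::rnorm(1, cfg$sbp_mean, cfg$sbp_sd)
    dbp <- stats::rnorm(1, cfg$dbp_mean, cfg$dbp_sd)
    if (dbp >= sbp - 20) dbp <- sbp - 20
    hr_free <- stats::runif(1, cfg$heart_rate_range[1], cfg$heart_rate_range[2])
    cs <- cfg$coupling_strength
    hr <- (1 - cs) * hr_free + cs * .hr_map(dbp)

    # beat-by-beat construction
    abp <- numeric(0); ecg <- numeric(0)
    truth_sbp <- numeric(0); truth_dbp <- numeric(0); onsets <- integer(0)
    while (length(abp) < n) {
      sbp_b <- sbp + if (cfg$beat_jitter_sd > 0) stats::rnorm(1, 0, cfg$beat_jitter_sd) else 0
      dbp_b <- dbp + if (cfg$beat_jitter_sd > 0) stats::rnorm(1, 0, cfg$beat_jitter_sd) else 0
      if (dbp_b >= sbp_b - 10) dbp_b <- sbp_b - 10
      n_beat <- max(10L, round(cfg$fs * 60 / hr))
      onsets <- c(onsets, length(abp) + 1L)
      truth_sbp <- c(truth_sbp, sbp_b); truth_dbp <- c(truth_dbp, dbp_b)
      abp <- c(abp, .abp_beat(sbp_b, dbp_b, n_beat, cfg$fs))
      amp_b <- (1 - cs) * 1 + cs * .amp_map(sbp_b)
      beat_ecg <- numeric(n_beat)
      sigma <- 0.02 * cfg$fs
      r_at <- round(0.05 * cfg$fs) + 1L
      tt <- seq_len(n_beat)
      beat_ecg <- amp_b * exp(-0.5 * ((tt - r_at) / sigma)^2)
      ecg <- c(ecg, beat_ecg)
    }
    keep_beats <- onsets <= n
    onsets <- onsets[keep_beats]
    truth_sbp <- truth_sbp[keep_beats]; truth_dbp <- truth_dbp[keep_beats]
    abp <- abp[seq_len(n)]; ecg <- ecg[seq_len(n)]

    # additive contaminations on the ECG only
    if (cfg$wander_amplitude > 0) {
      amp <- cfg$wander_amplitude * diff(range(ecg))
      phase <- stats::runif(1, 0, 2 * pi)
      t_s <- (seq_len(n) - 1) / cfg$fs
      ecg <- ecg + amp * sin(2 * pi * cfg$wander_freq_hz * t_s + phase)
    }
    if (cfg$hf_noise_sd > 0) {
      white <- stats::rnorm(n)
      bf <- signal::butter(4, 45 / (cfg$fs / 2), type = "high")
      hf <- signal::filtfilt(bf, white)
      hf <- hf / stats::sd(hf) * cfg$hf_noise_sd
      ecg <- ecg + hf
    }

    # artifact injection on whole 1-s ABP windows
    artifact_windows <- integer(0)
    if (cfg$artifact_rate > 0) {
      n_win <- floor(n / cfg$fs)
      hits <- which(stats::runif(n_win) < cfg$artifact_rate)
      artifact_windows <- hits
    }
    rec <- structure(
      list(ecg = ecg, abp = abp, fs = cfg$fs,
           truth_sbp = truth_sbp, truth_dbp = truth_dbp,
           beat_onsets = onsets, sbp = sbp, dbp = dbp, hr = hr,
           artifact_windows = integer(0), record_index = record_index),
      class = "signal_record"
    )
    for (w in artifact_windows) {
      rec <- inject_artifact(rec, w, seed = .derive_seed(cfg$seed, 1e6 + record_index * 1000 + w))
    }
    rec
  })
}

#' Replace one 1-s ABP window with a negative-skew artifact
#'
#' The addressed window is overwritten by a left-skewed disturbance (the
#' mirror image of a clean pulse train, plus small noise), giving a sample
#' skewness below zero so that the quality gate rejects the segment. All
#' other samples are untouched.
#'
#' @param record A `signal_record`.
#' @param window_index 1-based index of the 1-s ABP window.
#' @param seed Seed for the artifact noise.
#' @return The modified `signal_record`; `artifact_windows` records the hit.
#' @export
inject_artifact <- function(record, window_index, seed = 1L) {
  if (!inherits(record, "signal_record")) stop("`record` must be a signal_record")
  n_win <- floor(length(record$abp) / record$fs)
  if (window_index < 1L || window_index > n_win)
    stop(sprintf("window_index %d out of range [1, %d]", window_index, n_win))
  idx <- ((window_index - 1L) * record$fs + 1L):(window_index * record$fs)
  withr::with_seed(as.integer(seed), {
    record$abp[idx] <- .artifact_window(record$sbp, record$dbp, record$fs)
  })
  record$artifact_windows <- sort(unique(c(record$artifact_windows, as.integer(window_index))))
  record
}

#' Generate a dataset of records with a train/validation/test split
#'
#' Records are partitioned 80/10/10 (validation and test sizes rounded, the
#' remainder trains); the permutation is determined by `cfg$seed`.
#'
#' @param cfg A [sim_config()] with `n_records >= 10`.
#' @return An object of class `bp_dataset`: list of `records`, a `manifest`
#'   data frame (record_id, split, sbp, dbp, hr, n_artifact_windows) and the
#'   config.
#' @export
make_dataset <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config")
  n <- cfg$n_records
  if (n < 10L) stop("`n_records` must be at least 10 to realize an 80/10/10 split")
  records <- lapply(seq_len(n) - 1L, function(k) generate_record(cfg, k))
  n_val <- round(0.1 * n); n_test <- round(0.1 * n)
  split <- rep("train", n)
  perm <- withr::with_seed(.derive_seed(cfg$seed, 999983L), sample.int(n))
  split[perm[seq_len(n_val)]] <- "val"
  split[perm[n_val + seq_len(n_test)]] <- "test"
  manifest <- data.frame(
    record_id = vapply(records, function(r) r$record_index, integer(1)),
    split = split,
    sbp = vapply(records, function(r) r$sbp, numeric(1)),
    dbp = vapply(records, function(r) r$dbp, numeric(1)),
    hr = vapply(records, function(r) r$hr, numeric(1)),
    n_artifact_windows = vapply(records, function(r) length(r$artifact_windows), integer(1))
  )
  structure(list(records = records, manifest = manifest, cfg = cfg),
            class = "bp_dataset")
}

#' Write / read a signal record as plain CSV
#'
#' The waveform file has comment headers (`# fs=...`) followed by `ecg,abp`
#' columns; per-beat truth goes to a `_truth.csv` sidecar.
#'
#' @param record A `signal_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_record <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", record$fs), con)
  writeLines(sprintf("# record_index=%d", record$record_index), con)
  utils::write.csv(data.frame(ecg = record$ecg, abp = record$abp), con,
                   row.names = FALSE)
  truth <- data.frame(onset = record$beat_onsets,
                      sbp = record$truth_sbp, dbp = record$truth_dbp)
  utils::write.csv(truth, sub("\\.csv$", "_truth.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_record
#' @export
read_signal_record <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key, default = NA) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(sub(sprintf("^# %s=", key), "", m[1]))
  }
  dat <- utils::read.csv(path, comment.char = "#")
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else
    data.frame(onset = integer(0), sbp = numeric(0), dbp = numeric(0))
  structure(
    list(ecg = dat$ecg, abp = dat$abp, fs = get_field("fs", 125),
         truth_sbp = truth$sbp, truth_dbp = truth$dbp,
         beat_onsets = truth$onset,
         sbp = if (nrow(truth)) stats::median(truth$sbp) else NA_real_,
         dbp = if (nrow(truth)) stats::median(truth$dbp) else NA_real_,
         hr = NA_real_, artifact_windows = integer(0),
         record_index = as.integer(get_field("record_index", 0))),
    class = "signal_record"
  )
}
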