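# ECG preprocessing: wavelet denoise at the native rate, downsample to
# 100 Hz, crop both signals into aligned fixed-length windows, and min-max
# normalize the ECG. ABP is never rescaled: its absolute pressures are the
# ground truth.

#' Rational downsampling with anti-alias filtering
#'
#' Resamples `signal` from `fs_in` to `fs_out` with a polyphase FIR
#' resampler (125 to 100 Hz is the exact 4/5 ratio used throughout). Output
#' length is `round(length(signal) * fs_out / fs_in)`.
#'
#' @param signal Numeric series.
#' @param fs_in,fs_out Input and output sampling rates, Hz (`fs_out <= fs_in`).
#' @return The resampled series.
#' @examples
#' length(downsample(sin(seq_len(1250)), 125, 100)) # 1000
#' @export
downsample <- function(signal, fs_in, fs_out) {
  if (fs_out > fs_in) stop("`fs_out` must not exceed `fs_in`")
  if (fs_out == fs_in) return(as.numeric(signal))
  g <- .gcd(fs_out, fs_in)
  p <- fs_out / g; q <- fs_in / g
  out <- as.numeric(signal::resample(as.numeric(signal), p, q))
  n_out <- round(length(signal) * fs_out / fs_in)
  if (length(out) >= n_out) out[seq_len(n_out)]
  else c(out, rep(out[length(out)], n_out - length(out)))
}

.gcd <- function(a, b) {
  while (b > 1e-9) { t <- b; b <- a %% b; a <- t }
  a
}

#' Crop a synchronized ECG/ABP pair into aligned fixed-length windows
#'
#' Consecutive non-overlapping windows of exactly `duration_s` seconds; a
#' trailing remainder is discarded. The two signals may have different
#' sampling rates (ECG at 100 Hz after downsampling, ABP kept at 125 Hz);
#' windows are aligned in time.
#'
#' @param ecg,abp Numeric series covering the same time span.
#' @param fs_ecg,fs_abp Sampling rates, Hz.
#' @param duration_s Window length in seconds.
#' @return A list of window pairs, each
#'   `list(ecg, abp, start_index_ecg, start_index_abp)`; empty for input
#'   shorter than one window.
#' @export
segment_pair <- function(ecg, abp, fs_ecg, fs_abp, duration_s = 10) {
  n_ecg <- round(duration_s * fs_ecg); n_abp <- round(duration_s * fs_abp)
  if (n_ecg < 1 || n_abp < 1) stop("`duration_s` too short for the sampling rates")
  k <- min(length(ecg) %/% n_ecg, length(abp) %/% n_abp)
  if (k < 1) return(list())
  lapply(seq_len(k), function(i) {
    se <- (i - 1L) * n_ecg + 1L; sa <- (i - 1L) * n_abp + 1L
    list(ecg = ecg[se:(se + n_ecg - 1L)], abp = abp[sa:(sa + n_abp - 1L)],
         start_index_ecg = se, start_index_abp = sa)
  })
}

#' Min-max normalization to \[0, 1\]
#'
#' `(x - min) / (max - min)`; a constant window maps to all zeros by
#' convention (such windows carry no morphology).
#'
#' @param window Non-empty numeric series.
#' @return Series with min 0 and max 1 (non-constant input).
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(window) {
  if (!length(window)) stop("`window` must be non-empty")
  rng <- range(window)
  if (rng[2] - rng[1] <= 0) return(rep(0, length(window)))
  (window - rng[1]) / (rng[2] - rng[1])
}

#' Preprocess one record into aligned, normalized segments
#'
#' Applies the full chain denoise -> downsample -> segment -> normalize to
#' the ECG while keeping the ABP at its native rate and scale.
#'
#' @param record A `signal_record`.
#' @param spec A [wavelet_spec()] for the denoiser.
#' @param fs_out ECG sampling rate after downsampling, Hz.
#' @param duration_s Segment length, seconds.
#' @return List of segments: each
#'   `list(ecg, abp, fs_ecg, fs_abp, source_record, start_index)` with `ecg`
#'   normalized to `[0, 1]`.
#' @export
preprocess_record <- function(record, spec = wavelet_spec(), fs_out = 100,
                              duration_s = 10) {
  ecg_dn <- dwt_denoise(record$ecg, record$fs, spec)
  ecg_ds <- downsample(ecg_dn, record$fs, fs_out)
  wins <- segment_pair(ecg_ds, record$abp, fs_out, record$fs, duration_s)
  lapply(wins, function(w) {
    list(ecg = minmax_normalize(w$ecg), abp = w$abp,
         fs_ecg = fs_out, fs_abp = record$fs,
         source_record = record$record_index,
         start_index = w$start_index_ecg)
  })
}
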