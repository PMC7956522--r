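# Discrete wavelet transform with Daubechies-8, used to strip baseline wander
# and high-frequency noise from ECG before segmentation.

# db8 low-pass decomposition filter (16 taps, orthonormal). The other three
# filters follow from the quadrature-mirror relations of an orthogonal bank.
.DB8_DEC_LO <- c(
  -0.00011747678412476953, 0.0006754494064505693, -0.00039174037337694705,
  -0.004870352993451574, 0.008746094047405777, 0.013981027917398282,
  -0.044088253930794755, -0.017369301001807547, 0.12874742662047847,
  0.0004724845739132828, -0.2840155429615469, -0.015829105256349306,
  0.5853546836542067, 0.6756307362972898, 0.31287159091429995,
  0.05441584224310401
)

.db8_filters <- function() {
  dec_lo <- .DB8_DEC_LO
  rec_lo <- rev(dec_lo)
  dec_hi <- rec_lo * (-1)^(seq_along(rec_lo))
  rec_hi <- rev(dec_hi)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi)
}

#' Wavelet denoising specification
#'
#' Describes the dyadic decomposition used to band-limit ECG: the mother
#' wavelet, the decomposition depth, and which coefficient sets are zeroed
#' before reconstruction. The defaults (db8, 8 levels, zero the deepest
#' approximation and the first detail band) remove content below about
#' `fs/2 / 2^levels` Hz (baseline wander) and above `fs/4` Hz
#' (high-frequency noise) for a signal sampled at `fs`.
#'
#' @param mother Mother wavelet family; only `"db8"` is provided.
#' @param levels Decomposition depth (>= 1).
#' @param zeroed_approx_level Approximation level whose coefficients are
#'   zeroed (the deepest level), or `NA` to keep them.
#' @param zeroed_detail_levels Integer vector of detail levels to zero.
#' @return An object of class `wavelet_spec`.
#' @examples
#' spec <- wavelet_spec()
#' band_edges(125, spec)
#' @export
wavelet_spec <- function(mother = "db8", levels = 8L,
                         zeroed_approx_level = levels,
                         zeroed_detail_levels = 1L) {
  mother <- match.arg(mother, "db8")
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1")
  zd <- as.integer(zeroed_detail_levels)
  if (length(zd) && (any(zd < 1L) || any(zd > levels)))
    stop("zeroed detail levels must lie within [1, levels]")
  if (!is.na(zeroed_approx_level) && zeroed_approx_level != levels)
    stop("only the deepest approximation level can be zeroed")
  structure(
    list(mother = mother, levels = levels,
         zeroed_approx_level = zeroed_approx_level,
         zeroed_detail_levels = zd),
    class = "wavelet_spec"
  )
}

# full linear convolution
.conv_full <- function(x, f) {
  as.numeric(stats::convolve(x, rev(f), type = "open"))
}

# one analysis step with symmetric (half-sample) boundary extension;
# output length floor((n + L - 1)/2) per band
.dwt_step <- function(x, flt) {
  L <- length(flt$dec_lo)
  n <- length(x)
  xe <- c(rev(x[seq_len(L - 1L)]), x, rev(x[(n - L + 2L):n]))
  m <- (n + L - 1L) %/% 2L
  idx <- seq(L + 1L, by = 2L, length.out = m)
  list(cA = .conv_full(xe, flt$dec_lo)[idx],
       cD = .conv_full(xe, flt$dec_hi)[idx])
}

# one synthesis step: upsample, filter, sum, crop the boundary transient,
# then crop to the parent length recorded during analysis
.idwt_step <- function(cA, cD, flt, out_len) {
  L <- length(flt$rec_lo)
  m <- length(cA)
  stopifnot(length(cD) == m)
  up_a <- numeric(2L * m); up_a[seq(1L, 2L * m, by = 2L)] <- cA
  up_d <- numeric(2L * m); up_d[seq(1L, 2L * m, by = 2L)] <- cD
  y <- .conv_full(up_a, flt$rec_lo) + .conv_full(up_d, flt$rec_hi)
  y <- y[(L - 1L):(2L * m)]
  y[seq_len(out_len)]
}

# smallest signal length for which every analysis level sees >= L samples
.min_dwt_length <- function(levels, L = 16L) {
  m <- L
  for (l in seq_len(levels - 1L)) m <- 2L * m - (L - 1L)
  m
}

#' Multilevel DWT decomposition
#'
#' Decomposes a signal into `spec$levels` detail bands plus a final
#' approximation band using symmetric (half-sample) boundary extension.
#'
#' @param signal Numeric series.
#' @param spec A [wavelet_spec()].
#' @return A list with the approximation coefficients `a`, detail
#'   coefficients `d` (list, level 1 = finest), the per-level input lengths
#'   and the spec, suitable for [dwt_reconstruct()].
#' @export
dwt_decompose <- function(signal, spec = wavelet_spec()) {
  flt <- .db8_filters()
  L <- length(flt$dec_lo)
  min_len <- .min_dwt_length(spec$levels, L)
  if (length(signal) < min_len)
    stop(sprintf(
      "signal of length %d is too short for a %d-level decomposition; at least %d samples are required",
      length(signal), spec$levels, min_len))
  d <- vector("list", spec$levels)
  len_in <- integer(spec$levels)
  cur <- as.numeric(signal)
  for (l in seq_len(spec$levels)) {
    len_in[l] <- length(cur)
    step <- .dwt_step(cur, flt)
    d[[l]] <- step$cD
    cur <- step$cA
  }
  structure(list(a = cur, d = d, len_in = len_in, spec = spec),
            class = "dwt_decomposition")
}

#' Inverse multilevel DWT
#'
#' Reconstructs the signal from a [dwt_decompose()] result. With no
#' coefficients zeroed this inverts the analysis exactly (orthogonal
#' perfect-reconstruction bank).
#'
#' @param decomp A `dwt_decomposition`.
#' @return Numeric series of the original length.
#' @export
dwt_reconstruct <- function(decomp) {
  flt <- .db8_filters()
  cur <- decomp$a
  for (l in rev(seq_len(decomp$spec$levels))) {
    cur <- .idwt_step(cur, decomp$d[[l]], flt, decomp$len_in[l])
  }
  cur
}

#' Wavelet denoising of an ECG series
#'
#' Performs the `spec$levels`-deep db8 decomposition, zeroes the deepest
#' approximation band (baseline wander) and the listed detail bands
#' (high-frequency noise), and reconstructs. At 125 Hz with the default
#' 8-level spec the retained band is roughly 0.24 to 31.25 Hz
#' (see [band_edges()]).
#'
#' @param signal Numeric amplitude series.
#' @param fs Sampling rate in Hz (informational; the transform itself is
#'   rate-agnostic).
#' @param spec A [wavelet_spec()].
#' @return Denoised series of the same length.
#' @examples
#' t <- seq(0, 10, by = 1 / 125)
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 0.1 * t)
#' y <- dwt_denoise(x, 125)
#' @export
dwt_denoise <- function(signal, fs = 125, spec = wavelet_spec()) {
  decomp <- dwt_decompose(signal, spec)
  if (!is.na(spec$zeroed_approx_level)) decomp$a[] <- 0
  for (l in spec$zeroed_detail_levels) decomp$d[[l]][] <- 0
  dwt_reconstruct(decomp)
}

#' Retained frequency band of the denoiser
#'
#' Closed-form edges of the band kept by [dwt_denoise()]: the low cut is the
#' upper frequency of the deepest approximation band, `(fs/2)/2^levels`, and
#' the high cut is the lower frequency of the first detail band, `(fs/2)/2`.
#' Values are reported rounded to 2 decimals.
#'
#' @param fs Sampling rate in Hz (> 0).
#' @param spec A [wavelet_spec()].
#' @return Named numeric vector `c(low_cut, high_cut)` in Hz.
#' @examples
#' band_edges(125, wavelet_spec()) # c(0.24, 31.25)
#' @export
band_edges <- function(fs, spec = wavelet_spec()) {
  if (fs <= 0) stop("`fs` must be positive")
  nyq <- fs / 2
  c(low_cut = round(nyq / 2^spec$levels, 2), high_cut = round(nyq / 2, 2))
}
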