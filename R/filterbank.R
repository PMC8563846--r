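#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
NULL

#' Octave-band center frequencies of the analysis filterbank
#'
#' Eight one-octave bands from 125 Hz to 16 kHz, the grid on which spectral
#' energy profiles and spectral-slope colorations are defined.
#' @export
octave_centers_hz <- function() {
  c(125, 250, 500, 1000, 2000, 4000, 8000, 16000)
}

# Geometric octave band edges: center/sqrt(2) .. center*sqrt(2); the top band
# is capped just below Nyquist.
octave_band_edges <- function(rate = 44100) {
  centers <- octave_centers_hz()
  tibble(
    center_hz = centers,
    lo_hz = centers / sqrt(2),
    hi_hz = pmin(centers * sqrt(2), 0.999 * rate / 2)
  )
}

# Complex (causal) or squared-magnitude (zero-phase) frequency response of a
# Butterworth band-pass of the given design order, evaluated at frequencies f.
# The band-pass is the analog prototype 1/(1 + Omega^(2n)) under the standard
# lowpass-to-bandpass substitution Omega = (f^2 - lo*hi) / (f * (hi - lo)).
# Zero-phase mode returns |H|^2 (one forward-backward pass), causal mode the
# complex H itself.
butter_bandpass_response <- function(f, lo_hz, hi_hz, order = 5L,
                                     mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  fs <- pmax(f, .Machine$double.eps)
  om <- (fs^2 - lo_hz * hi_hz) / (fs * (hi_hz - lo_hz))
  if (mode == "zero_phase") {
    g <- 1 / (1 + om^(2 * order))
    g[f <= 0] <- 0
    return(g)
  }
  k <- seq_len(order)
  poles <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  s <- 1i * om
  h <- rep(prod(-poles), length(s))
  for (p in poles) h <- h / (s - p)
  h[f <= 0] <- 0 + 0i
  h
}

# Frequencies of the full FFT grid folded onto [0, rate/2], so that a gain
# computed at fold_freqs() is Hermitian-symmetric when applied to fft(x).
fold_freqs <- function(n, rate) {
  f <- (seq_len(n) - 1) * rate / n
  pmin(f, rate - f)
}

#' Octave-band RMS energy levels of a waveform
#'
#' Feeds the signal through the 5th-order Butterworth octave filterbank
#' (125 Hz--16 kHz centers) and returns the RMS energy level of each band in
#' dB. Band powers are computed spectrally via Parseval's theorem, which for
#' the zero-phase filter mode is exact.
#'
#' @param wave numeric waveform, full scale +-1.
#' @param rate sampling rate in Hz.
#' @param order Butterworth design order.
#' @param mode `"zero_phase"` (forward-backward, default) or `"causal"`.
#' @return A tibble with columns `center_hz` and `level_db` (8 rows).
#' @export
octave_band_levels <- function(wave, rate = 44100, order = 5L,
                               mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (length(wave) == 0 || all(wave == 0)) {
    abort("octave_band_levels() needs a non-silent waveform (log of zero energy).")
  }
  n <- length(wave)
  x <- stats::fft(wave)
  ff <- fold_freqs(n, rate)
  edges <- octave_band_edges(rate)
  pw <- vapply(seq_len(nrow(edges)), function(b) {
    g <- butter_bandpass_response(ff, edges$lo_hz[b], edges$hi_hz[b],
                                  order = order, mode = mode)
    sum(Mod(x * g)^2) / n^2
  }, numeric(1))
  tibble(center_hz = edges$center_hz, level_db = 10 * log10(pw))
}

# Per-band slope gains in dB: slope * log2(center/pivot) inside the active
# region, held at the boundary value outside it. Methods-style default keeps
# the 16 kHz band at the 8 kHz gain; extend_to_16k = TRUE slopes it too.
slope_band_gains_db <- function(slope_db_per_oct, pivot_hz = 1000,
                                active_lo_hz = 125, active_hi_hz = 8000,
                                extend_to_16k = FALSE) {
  centers <- octave_centers_hz()
  hi <- if (extend_to_16k) 16000 else active_hi_hz
  cl <- pmin(pmax(centers, active_lo_hz), hi)
  slope_db_per_oct * log2(cl / pivot_hz)
}

# Composite analysis-synthesis gain curve over a folded frequency grid:
# the per-band filter responses weighted by linear slope gains and summed.
slope_gain_curve <- function(ff, slope_db_per_oct, rate = 44100, order = 5L,
                             mode = "zero_phase", pivot_hz = 1000,
                             extend_to_16k = FALSE) {
  edges <- octave_band_edges(rate)
  gains <- 10^(slope_band_gains_db(slope_db_per_oct, pivot_hz = pivot_hz,
                                   extend_to_16k = extend_to_16k) / 20)
  total <- if (mode == "zero_phase") numeric(length(ff)) else complex(length(ff))
  for (b in seq_len(nrow(edges))) {
    total <- total + gains[b] *
      butter_bandpass_response(ff, edges$lo_hz[b], edges$hi_hz[b],
                               order = order, mode = mode)
  }
  total
}

#' Apply a spectral-slope coloration through the octave filterbank
#'
#' Decomposes the waveform with the 5th-order Butterworth octave filterbank,
#' scales each band by `slope_db_per_oct * log2(center/pivot)` dB (active
#' between 125 Hz and 8 kHz, boundary gains held outside), and remixes.
#' A slope of 0 passes the signal through the analysis--synthesis chain with a
#' magnitude response flat within +-1 dB over the active region.
#'
#' @param wave numeric waveform.
#' @param slope_db_per_oct filter slope in dB per octave (|slope| <= `max_abs_slope`).
#' @param rate sampling rate in Hz.
#' @param pivot_hz balance point receiving 0 dB gain.
#' @param mode filter mode, `"zero_phase"` or `"causal"`.
#' @param extend_to_16k if `TRUE` the sloped region extends to the 16 kHz band.
#' @param order Butterworth design order.
#' @param max_abs_slope largest admissible |slope|.
#' @return The recolored waveform (same length as the input).
#' @export
apply_spectral_slope <- function(wave, slope_db_per_oct, rate = 44100,
                                 pivot_hz = 1000,
                                 mode = c("zero_phase", "causal"),
                                 extend_to_16k = FALSE, order = 5L,
                                 max_abs_slope = 6) {
  mode <- match.arg(mode)
  if (abs(slope_db_per_oct) > max_abs_slope) {
    abort(sprintf("|slope| = %.2f dB/oct exceeds max_abs_slope = %.1f.",
                  abs(slope_db_per_oct), max_abs_slope))
  }
  n <- length(wave)
  ff <- fold_freqs(n, rate)
  g <- slope_gain_curve(ff, slope_db_per_oct, rate = rate, order = order,
                        mode = mode, pivot_hz = pivot_hz,
                        extend_to_16k = extend_to_16k)
  Re(stats::fft(stats::fft(wave) * g, inverse = TRUE)) / n
}
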