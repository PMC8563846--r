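#' Construct an acoustic transfer function
#'
#' A transfer function is stored as a mono impulse response at a fixed
#' sampling rate; frequency-domain views are derived on demand on an FFT grid.
#'
#' @param ir numeric impulse response.
#' @param rate sampling rate in Hz.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(ir, rate = 44100) {
  ir <- as.numeric(ir)
  if (length(ir) == 0 || !all(is.finite(ir))) {
    abort("transfer_function() needs a finite, non-empty impulse response.")
  }
  structure(list(ir = ir, rate = rate), class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function: %d taps @ %g Hz>\n", length(x$ir), x$rate))
  invisible(x)
}

#' Complex frequency response of a transfer function
#'
#' @param tf a [transfer_function()].
#' @param n_fft FFT grid length (>= impulse-response length).
#' @return Complex vector of length `n_fft`.
#' @export
tf_frequency_response <- function(tf, n_fft) {
  stopifnot(inherits(tf, "transfer_function"))
  if (n_fft < length(tf$ir)) {
    abort("n_fft must be at least the impulse-response length.")
  }
  stats::fft(c(tf$ir, numeric(n_fft - length(tf$ir))))
}

# Default morph grid: next power of two >= twice the longer impulse response.
default_morph_nfft <- function(tf_a, tf_b) {
  2^ceiling(log2(2 * max(length(tf_a$ir), length(tf_b$ir))))
}

# 2*pi-jump phase unwrapping along the frequency axis, starting at DC.
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  p[1] + cumsum(c(0, dp))
}

#' Morph between two acoustic transfer functions
#'
#' Linear inter-/extrapolation in the spectral log-magnitude domain and the
#' unwrapped phase domain: `|H_m| (dB) = (1-m) |H_a| (dB) + m |H_b| (dB)` and
#' likewise for the unwrapped phase. A morph level of 0 reproduces `tf_a`
#' (the hear-through Device in the experiments), 1 reproduces `tf_b` (the
#' Open Ear); levels outside `[0, 1]` exaggerate one or the other.
#'
#' @param tf_a,tf_b [transfer_function()] objects on the same sampling rate.
#' @param m morph level (dimensionless; the experiments use `[-0.5, 1.5]`).
#' @param n_fft FFT grid; defaults to the next power of two at least twice the
#'   longer impulse response.
#' @return A [transfer_function()] whose impulse response lives on the morph grid.
#' @export
morph_transfer_functions <- function(tf_a, tf_b, m, n_fft = NULL) {
  stopifnot(inherits(tf_a, "transfer_function"), inherits(tf_b, "transfer_function"))
  if (!isTRUE(all.equal(tf_a$rate, tf_b$rate))) {
    abort("Transfer functions are on different sampling rates (grid mismatch).")
  }
  if (is.null(n_fft)) n_fft <- default_morph_nfft(tf_a, tf_b)
  ha <- tf_frequency_response(tf_a, n_fft)
  hb <- tf_frequency_response(tf_b, n_fft)
  half <- seq_len(n_fft %/% 2 + 1)
  ma <- Mod(ha[half]); mb <- Mod(hb[half])
  bad <- which(ma == 0 | mb == 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Zero magnitude at FFT bin %d: log-magnitude morphing is undefined there.",
      bad[1]))
  }
  lm <- (1 - m) * log(ma) + m * log(mb)
  pm <- (1 - m) * unwrap_phase(Arg(ha[half])) + m * unwrap_phase(Arg(hb[half]))
  hm_half <- exp(lm) * exp(1i * pm)
  hm <- complex(length.out = n_fft)
  hm[half] <- hm_half
  if (n_fft %/% 2 > 1) {
    hm[seq(n_fft, n_fft %/% 2 + 2)] <- Conj(hm_half[2:(n_fft %/% 2)])
  }
  ir <- Re(stats::fft(hm, inverse = TRUE)) / n_fft
  transfer_function(ir, rate = tf_a$rate)
}

#' Convolve a waveform with a transfer function
#'
#' Linear (FFT-based) convolution, truncated to the input length. If the
#' convolution would clip full scale, the output is re-normalized to a peak of
#' 0.999 and a message is emitted.
#'
#' @param wave numeric waveform.
#' @param tf a [transfer_function()].
#' @return Filtered waveform, same length as `wave`.
#' @export
apply_transfer_function <- function(wave, tf) {
  stopifnot(inherits(tf, "transfer_function"))
  n <- length(wave)
  m <- length(tf$ir)
  nf <- stats::nextn(n + m - 1, 2)
  y <- Re(stats::fft(
    stats::fft(c(wave, numeric(nf - n))) * stats::fft(c(tf$ir, numeric(nf - m))),
    inverse = TRUE)) / nf
  y <- y[seq_len(n)]
  peak <- max(abs(y))
  if (peak > 1) {
    message(sprintf("apply_transfer_function(): peak %.3f would clip; re-normalized to 0.999.", peak))
    y <- y * (0.999 / peak)
  }
  y
}
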