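#' ERB-number (Cam) scale
#'
#' Glasberg--Moore mapping between frequency in Hz and ERB number.
#' @param f_hz frequency in Hz.
#' @return ERB number (Cam).
#' @export
erb_number <- function(f_hz) 21.4 * log10(4.37 * f_hz / 1000 + 1)

#' @rdname erb_number
#' @param cam ERB number.
#' @export
erb_number_inv <- function(cam) (10^(cam / 21.4) - 1) * 1000 / 4.37

#' ERB bandwidth at a given frequency
#' @param f_hz frequency in Hz.
#' @return Equivalent rectangular bandwidth in Hz.
#' @export
erb_bandwidth <- function(f_hz) 24.7 * (4.37 * f_hz / 1000 + 1)

#' Center frequencies of the ERB filterbank
#'
#' `n_bands` centers uniformly spaced on the ERB-number scale between `f_lo`
#' and `f_hi`.
#' @param n_bands number of bands.
#' @param f_lo,f_hi frequency range in Hz.
#' @export
erb_centers <- function(n_bands = 128, f_lo = 25, f_hi = 20000) {
  erb_number_inv(seq(erb_number(f_lo), erb_number(f_hi), length.out = n_bands))
}

# Grouping geometry for an FFT half-grid: for every positive-frequency bin the
# (fractional) position on the uniform Cam grid of centers. Cached per call
# site; cheap enough to recompute.
erb_bin_positions <- function(n, rate, n_bands = 128, f_lo = 25, f_hi = 20000) {
  nh <- n %/% 2 + 1
  f <- (seq_len(nh) - 1) * rate / n
  cams <- erb_number(f)
  c1 <- erb_number(f_lo)
  dc <- (erb_number(f_hi) - c1) / (n_bands - 1)
  pos <- (cams - c1) / dc + 1
  pmin(pmax(pos, 1), n_bands)
}

# Core grouping: pool FFT half-grid magnitudes (already floored) into bands.
group_magnitudes <- function(mag, pos, n_bands, grouping = "nearest") {
  e <- numeric(n_bands)
  if (grouping == "nearest") {
    idx <- as.integer(round(pos))
    s <- rowsum(mag, idx)
    e[as.integer(rownames(s))] <- s[, 1]
  } else {
    lo <- pmin(floor(pos), n_bands - 1)
    fr <- pos - lo
    s1 <- rowsum(mag * (1 - fr), lo)
    s2 <- rowsum(mag * fr, lo + 1)
    e[as.integer(rownames(s1))] <- e[as.integer(rownames(s1))] + s1[, 1]
    e[as.integer(rownames(s2))] <- e[as.integer(rownames(s2))] + s2[, 1]
  }
  e
}

# dBFS floor applied to FFT half-grid magnitudes: bin level is
# 20*log10(2*|X|/N) (factor 2 for the one-sided spectrum; 1 at DC and
# Nyquist, which have no mirror bin) so a full-scale sinusoid reads ~0 dBFS
# and a DC offset reads its amplitude. Bins below floor_dbfs are zeroed.
floor_magnitudes <- function(mag, n, floor_dbfs = -90) {
  scale <- rep(2, length(mag))
  scale[1] <- 1
  if (n %% 2 == 0) scale[length(mag)] <- 1
  mag[mag * scale < 10^(floor_dbfs / 20) * n] <- 0
  mag
}

#' ERB-grouped magnitude spectrum of a waveform
#'
#' Computes a single FFT over the whole excerpt (no windowing), zeroes all
#' bin magnitudes below `floor_dbfs` (dB re full scale, with a full-scale
#' sinusoid at ~0 dBFS), and pools the remaining linear magnitudes into
#' `n_bands` bands spaced uniformly on the ERB-number scale.
#'
#' @param wave numeric waveform.
#' @param rate sampling rate in Hz.
#' @param n_bands number of ERB bands.
#' @param floor_dbfs magnitude floor in dB full scale.
#' @param f_lo,f_hi frequency range of the band centers in Hz.
#' @param grouping `"nearest"` pools each bin into the band whose center is
#'   nearest on the ERB scale; `"triangular"` splits each bin linearly between
#'   the two neighbouring centers.
#' @return A tibble with columns `band`, `center_hz`, `magnitude`.
#' @export
erb_spectrum <- function(wave, rate = 44100, n_bands = 128, floor_dbfs = -90,
                         f_lo = 25, f_hi = 20000,
                         grouping = c("nearest", "triangular")) {
  grouping <- match.arg(grouping)
  if (length(wave) == 0) abort("erb_spectrum() needs a non-empty signal.")
  n <- length(wave)
  nh <- n %/% 2 + 1
  mag <- Mod(stats::fft(wave))[seq_len(nh)]
  mag <- floor_magnitudes(mag, n, floor_dbfs)
  pos <- erb_bin_positions(n, rate, n_bands, f_lo, f_hi)
  e <- group_magnitudes(mag, pos, n_bands, grouping)
  tibble(band = seq_len(n_bands),
         center_hz = erb_centers(n_bands, f_lo, f_hi),
         magnitude = e)
}

#' Spectral centroid of an ERB spectrum
#'
#' The amplitude-weighted mean of the band center frequencies,
#' `SC = sum(f_j E_j) / sum(E_j)`: the model's brightness feature.
#'
#' @param spectrum a tibble as returned by [erb_spectrum()] (columns
#'   `center_hz`, `magnitude`).
#' @return The centroid in Hz.
#' @export
spectral_centroid <- function(spectrum) {
  e <- spectrum$magnitude
  if (any(e < 0) || !all(is.finite(e))) {
    abort("spectral_centroid() needs finite, nonnegative magnitudes.")
  }
  if (sum(e) <= 0) {
    abort("spectral_centroid() is undefined for an all-zero spectrum.")
  }
  sum(spectrum$center_hz * e) / sum(e)
}

#' Spectral centroid of a waveform
#'
#' Convenience wrapper: [erb_spectrum()] followed by [spectral_centroid()].
#' @inheritParams erb_spectrum
#' @export
sc_hz <- function(wave, rate = 44100, n_bands = 128, floor_dbfs = -90,
                  f_lo = 25, f_hi = 20000,
                  grouping = c("nearest", "triangular")) {
  spectral_centroid(erb_spectrum(wave, rate, n_bands, floor_dbfs, f_lo, f_hi,
                                 match.arg(grouping)))
}

# SC from a precomputed FFT half-grid magnitude vector (shared fast path).
sc_from_half_magnitudes <- function(mag, n, pos, centers, floor_dbfs = -90,
                                    grouping = "nearest") {
  mag <- floor_magnitudes(mag, n, floor_dbfs)
  e <- group_magnitudes(mag, pos, length(centers), grouping)
  if (sum(e) <= 0) abort("spectral centroid undefined: all-zero spectrum.")
  sum(centers * e) / sum(e)
}

#' Spectral-centroid table for slope-filtered excerpts
#'
#' Computes the SC of every excerpt in a corpus under each spectral-slope
#' coloration (plus the unprocessed excerpt, reported as coloration `NA`).
#' Exploits the linearity of the filterbank: the FFT of the slope-filtered
#' signal equals the excerpt FFT times the composite slope gain curve, so one
#' FFT per excerpt serves all slopes. Numerically identical to running
#' [apply_spectral_slope()] followed by [sc_hz()].
#'
#' @param corpus a corpus tibble with columns `excerpt_id` and `wave` (list).
#' @param slopes numeric vector of filter slopes in dB/oct.
#' @param rate sampling rate in Hz.
#' @param include_raw also compute SC of the unprocessed excerpts.
#' @param ... passed on to the slope gain curve / ERB settings
#'   (`pivot_hz`, `extend_to_16k`, `mode`, `n_bands`, `floor_dbfs`, `grouping`).
#' @return A tibble with columns `excerpt_id`, `coloration`, `sc_hz`.
#' @export
sc_slope_table <- function(corpus, slopes, rate = 44100, include_raw = TRUE,
                           pivot_hz = 1000, extend_to_16k = FALSE,
                           mode = "zero_phase", n_bands = 128,
                           floor_dbfs = -90, grouping = "nearest") {
  stopifnot(all(c("excerpt_id", "wave") %in% names(corpus)))
  lens <- lengths(corpus$wave)
  geom <- list()
  curves <- list()
  for (n in unique(lens)) {
    key <- as.character(n)
    geom[[key]] <- erb_bin_positions(n, rate, n_bands)
    ff <- fold_freqs(n, rate)[seq_len(n %/% 2 + 1)]
    curves[[key]] <- lapply(slopes, function(s) {
      Mod(slope_gain_curve(ff, s, rate = rate, mode = mode, pivot_hz = pivot_hz,
                           extend_to_16k = extend_to_16k))
    })
  }
  centers <- erb_centers(n_bands)
  out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    w <- corpus$wave[[i]]
    n <- length(w)
    key <- as.character(n)
    mag <- Mod(stats::fft(w))[seq_len(n %/% 2 + 1)]
    cols <- c(if (include_raw) NA_real_, slopes)
    scs <- vapply(seq_along(cols), function(j) {
      m <- if (is.na(cols[j])) mag else mag * curves[[key]][[j - include_raw]]
      sc_from_half_magnitudes(m, n, geom[[key]], centers, floor_dbfs, grouping)
    }, numeric(1))
    out[[i]] <- tibble(excerpt_id = corpus$excerpt_id[i],
                       coloration = cols, sc_hz = scs)
  }
  dplyr::bind_rows(out)
}

#' Spectral-centroid table for morph-filtered excerpts
#'
#' Convolves every excerpt with the transfer function morphed at each level
#' (truncated linear convolution, as presented to listeners) and computes the
#' SC of the result. The unprocessed excerpt is reported as coloration `NA`.
#'
#' @param corpus a corpus tibble with columns `excerpt_id` and `wave` (list).
#' @param tf_pair a list with elements `device` and `open_ear`
#'   ([transfer_function()] objects).
#' @param morph_levels numeric morph levels.
#' @param include_raw also compute SC of the unprocessed excerpts.
#' @inheritParams sc_slope_table
#' @return A tibble with columns `excerpt_id`, `coloration`, `sc_hz`.
#' @export
sc_morph_table <- function(corpus, tf_pair, morph_levels, rate = 44100,
                           include_raw = TRUE, n_bands = 128,
                           floor_dbfs = -90, grouping = "nearest") {
  stopifnot(all(c("excerpt_id", "wave") %in% names(corpus)))
  tfs <- lapply(morph_levels, function(m) {
    morph_transfer_functions(tf_pair$device, tf_pair$open_ear, m)
  })
  out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    w <- corpus$wave[[i]]
    scs <- vapply(tfs, function(tf) {
      sc_hz(suppressMessages(apply_transfer_function(w, tf)),
            rate = rate, n_bands = n_bands, floor_dbfs = floor_dbfs,
            grouping = grouping)
    }, numeric(1))
    raw <- if (include_raw) {
      sc_hz(w, rate = rate, n_bands = n_bands, floor_dbfs = floor_dbfs,
            grouping = grouping)
    }
    out[[i]] <- tibble(excerpt_id = corpus$excerpt_id[i],
                       coloration = c(if (include_raw) NA_real_, morph_levels),
                       sc_hz = c(raw, scs))
  }
  dplyr::bind_rows(out)
}

#' Median spectral centroid of the unprocessed excerpts of a corpus
#'
#' The long-term reference used by the fixed-criterion model: the median SC
#' over all unfiltered stimuli of a domain.
#' @param sc_table a table from [sc_slope_table()] or [sc_morph_table()]
#'   containing `coloration = NA` rows, or a corpus tibble with `wave`.
#' @param rate sampling rate (used when a corpus is supplied).
#' @export
domain_median_sc <- function(sc_table, rate = 44100) {
  if ("wave" %in% names(sc_table)) {
    scs <- vapply(sc_table$wave, sc_hz, numeric(1), rate = rate)
    return(stats::median(scs))
  }
  raw <- sc_table$sc_hz[is.na(sc_table$coloration)]
  if (length(raw) == 0) {
    abort("domain_median_sc() needs unprocessed (coloration = NA) rows or waveforms.")
  }
  stats::median(raw)
}
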