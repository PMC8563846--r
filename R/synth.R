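# Corpus target spectrum: octave-band levels (dB, arbitrary reference) of the
# grand mean music profile the generator scatters around. Music-like: energy
# concentrated between 250 Hz and 2 kHz, rolling off at the extremes.
music_grand_profile_db <- function() {
  c(-12, -7, -5, -6, -8, -11, -15, -20)
}

# 50-ms raised-cosine fade applied in place at both ends.
apply_ramps <- function(wave, rate = 44100, ramp_s = 0.05) {
  nr <- round(ramp_s * rate)
  if (2 * nr > length(wave)) abort("waveform shorter than the two ramps")
  w <- raised_cosine_ramp(nr)
  wave[seq_len(nr)] <- wave[seq_len(nr)] * w
  idx <- seq(length(wave), length(wave) - nr + 1)
  wave[idx] <- wave[idx] * w
  wave
}

# The onset ramp template: 0 at the boundary sample, approaching 1.
raised_cosine_ramp <- function(n) {
  0.5 * (1 - cos(pi * (seq_len(n) - 1) / n))
}

peak_normalize <- function(wave, peak_dbfs = -3) {
  wave / max(abs(wave)) * 10^(peak_dbfs / 20)
}

# Synthesize one music-like excerpt: an octave-band-shaped noise bed plus a
# few harmonic tones with slow amplitude modulation. The band profile (dB,
# 8 octave centers) controls the long-term spectrum; tones follow the same
# envelope so band statistics stay close to the target.
synth_music_excerpt <- function(n, profile_db, rate = 44100,
                                tone_fraction = 0.35) {
  centers <- octave_centers_hz()
  nh <- n %/% 2
  f <- (seq_len(nh - 1)) * rate / n  # bins 1 .. nh-1 (exclude DC, Nyquist)
  env_db <- stats::approx(log2(centers), profile_db, xout = log2(pmax(f, 60)),
                          rule = 2)$y
  # band RMS level L implies PSD ~ 10^(L/10) / bandwidth; octave bandwidth ~ 0.707 f
  mag <- 10^(env_db / 20) / sqrt(pmax(f, 60))
  spec <- complex(length.out = n)
  spec[2:nh] <- complex(real = stats::rnorm(nh - 1), imaginary = stats::rnorm(nh - 1)) * mag
  spec[seq(n, n - nh + 2)] <- Conj(spec[2:nh])
  noise <- Re(stats::fft(spec, inverse = TRUE)) / n

  k <- sample(4:8, 1)
  f0 <- stats::runif(k, 100, 400)
  tspec <- complex(length.out = n)
  for (f0i in f0) {
    fh <- seq(f0i, 5000, by = f0i)
    bins <- pmin(pmax(round(fh * n / rate), 1), nh - 1)
    amp <- 10^(stats::approx(log2(centers), profile_db,
                             xout = log2(fh), rule = 2)$y / 20)
    tspec[bins + 1] <- tspec[bins + 1] +
      amp * exp(1i * stats::runif(length(bins), 0, 2 * pi))
  }
  tspec[seq(n, n - nh + 2)] <- Conj(tspec[2:nh])
  tones <- Re(stats::fft(tspec, inverse = TRUE)) / n
  t <- (seq_len(n) - 1) / rate
  am <- 1 + 0.8 * sin(2 * pi * stats::runif(1, 2, 8) * t + stats::runif(1, 0, 2 * pi))
  tones <- tones * am
  tr <- sqrt(mean(tones^2))
  if (tr > 0) tones <- tones * (tone_fraction * sqrt(mean(noise^2)) / tr)

  peak_normalize(apply_ramps(noise + tones, rate))
}

#' Generate a music-like audio corpus
#'
#' Synthesizes `n_excerpts` broadband music-like excerpts whose octave-band
#' profiles scatter around a fixed corpus target profile. The spread is
#' calibrated so that the mean (over excerpts) of the mean absolute per-band
#' deviation from the corpus grand mean approximates `heterogeneity_db` --
#' the homogeneity statistic on which real-corpus excerpt selection operates.
#'
#' @param n_excerpts number of excerpts (>= 1).
#' @param duration_s excerpt duration; one of 1, 2, 4 or 8 s.
#' @param seed RNG seed; corpora are a pure function of the arguments.
#' @param heterogeneity_db target mean absolute band deviation in dB.
#' @param rate sampling rate in Hz.
#' @param tone_fraction RMS of the tonal component relative to the noise bed.
#' @return A corpus tibble: `excerpt_id`, `domain`, `speaker_id`,
#'   `duration_s`, `rate`, `wave` (list-column of waveforms).
#' @export
generate_music_corpus <- function(n_excerpts, duration_s = 2, seed = 1,
                                  heterogeneity_db = 1.8, rate = 44100,
                                  tone_fraction = 0.35) {
  if (!duration_s %in% c(1, 2, 4, 8)) {
    abort(sprintf("duration_s must be one of 1, 2, 4, 8 s (got %s).",
                  format(duration_s)))
  }
  stopifnot(n_excerpts >= 1)
  profile <- music_grand_profile_db()
  # per-band offsets are N(0, s); the deviation statistic is computed on
  # row-centered profiles against the corpus grand mean, so
  # E[mean_b |dev|] = s * sqrt(7/8) * sqrt(2/pi). The log-frequency
  # interpolation of the synthesis envelope lets neighbouring bands bleed
  # into each octave measurement, shrinking realized deviations by ~0.76;
  # both factors are inverted here.
  s <- heterogeneity_db / (sqrt(7 / 8) * sqrt(2 / pi)) / 0.763
  n <- round(duration_s * rate)
  withr::with_seed(seed, {
    waves <- lapply(seq_len(n_excerpts), function(i) {
      synth_music_excerpt(n, profile + stats::rnorm(8, 0, s), rate,
                          tone_fraction)
    })
  })
  tibble(
    excerpt_id = sprintf("mus%gs_%04d", duration_s, seq_len(n_excerpts)),
    domain = "music",
    speaker_id = NA_character_,
    duration_s = duration_s,
    rate = rate,
    wave = waves
  )
}

# Truncated-normal sampler via inverse-CDF (exact, vectorized).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# One speech-like excerpt: harmonic complex with formant-like spectral peaks,
# a -6 dB/oct source tilt, a shaped noise floor and a syllabic envelope.
synth_speech_excerpt <- function(n, f0, formants, rate = 44100,
                                 extra_tilt_db_per_oct = 0) {
  nh <- n %/% 2
  env_db <- function(f) {
    -6 * log2(pmax(f, 100) / 100) +
      extra_tilt_db_per_oct * log2(pmax(f, 100) / 1000) * -1 +
      Reduce(`+`, lapply(formants, function(ff) {
        15 * exp(-0.5 * (log2(f / ff) / 0.22)^2)
      }))
  }
  fh <- seq(f0, 8000, by = f0)
  bins <- pmin(pmax(round(fh * n / rate), 1), nh - 1)
  spec <- complex(length.out = n)
  amp <- 10^(env_db(fh) / 20)
  spec[bins + 1] <- amp * exp(1i * stats::runif(length(bins), 0, 2 * pi))
  # shaped aspiration-noise floor, ~25 dB under the harmonics
  f <- (seq_len(nh - 1)) * rate / n
  nmag <- 10^((env_db(f) - 25) / 20) / sqrt(pmax(f, 100))
  spec[2:nh] <- spec[2:nh] +
    complex(real = stats::rnorm(nh - 1), imaginary = stats::rnorm(nh - 1)) * nmag
  spec[seq(n, n - nh + 2)] <- Conj(spec[2:nh])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  t <- (seq_len(n) - 1) / rate
  syl <- 1 - 0.6 * (0.5 + 0.5 * sin(2 * pi * stats::runif(1, 2.5, 5) * t +
                                      stats::runif(1, 0, 2 * pi)))
  peak_normalize(apply_ramps(x * syl, rate))
}

#' Generate a speech-like audio corpus
#'
#' Synthesizes sentence-like excerpts for `n_speakers_per_gender` male and as
#' many female speakers. Durations are drawn from a truncated normal (mean
#' 2.0 s, SD 0.26 s, clipped to 1.4--2.8 s). Male-labelled speakers receive a
#' lower fundamental and an extra downward spectral tilt, giving the
#' gender-specific spectral balance seen in real matrix-sentence material.
#'
#' @param n_speakers_per_gender speakers per gender (>= 1).
#' @param n_sentences_per_speaker sentences per speaker (>= 1).
#' @param seed RNG seed.
#' @param gender_tilt_db_per_oct extra downward tilt for male speakers.
#' @param rate sampling rate in Hz.
#' @return A corpus tibble as in [generate_music_corpus()], `domain = "speech"`,
#'   with `speaker_id` set on every excerpt.
#' @export
generate_speech_corpus <- function(n_speakers_per_gender,
                                   n_sentences_per_speaker, seed = 1,
                                   gender_tilt_db_per_oct = 3, rate = 44100) {
  stopifnot(n_speakers_per_gender >= 1, n_sentences_per_speaker >= 1)
  withr::with_seed(seed, {
    speakers <- tibble(
      speaker_id = c(sprintf("m%02d", seq_len(n_speakers_per_gender)),
                     sprintf("f%02d", seq_len(n_speakers_per_gender))),
      gender = rep(c("male", "female"), each = n_speakers_per_gender),
      f0 = c(stats::rnorm(n_speakers_per_gender, 120, 10),
             stats::rnorm(n_speakers_per_gender, 210, 15)),
      f1 = stats::runif(2 * n_speakers_per_gender, 350, 800),
      f2 = stats::runif(2 * n_speakers_per_gender, 1000, 2000),
      f3 = stats::runif(2 * n_speakers_per_gender, 2200, 3000)
    )
    rows <- list()
    for (i in seq_len(nrow(speakers))) {
      sp <- speakers[i, ]
      dur <- rtrunc_norm(n_sentences_per_speaker, 2.0, 0.26, 1.4, 2.8)
      tilt <- if (sp$gender == "male") gender_tilt_db_per_oct else 0
      # sample counts snapped to multiples of 420 = 2^2*3*5*7 so the excerpt
      # FFTs factor into small primes (duration granularity < 10 ms)
      waves <- lapply(420 * round(dur * rate / 420), function(n) {
        synth_speech_excerpt(n, sp$f0, list(sp$f1, sp$f2, sp$f3), rate, tilt)
      })
      rows[[i]] <- tibble(
        excerpt_id = sprintf("spe_%s_%03d", sp$speaker_id,
                             seq_len(n_sentences_per_speaker)),
        domain = "speech",
        speaker_id = sp$speaker_id,
        duration_s = vapply(waves, length, integer(1)) / rate,
        rate = rate,
        wave = waves
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' Generate a synthetic Device / Open-Ear transfer-function pair
#'
#' Two smooth minimum-phase transfer functions emulating an open-ear dummy
#' head response and a hear-through earphone response: relative to the open
#' ear, the device amplifies low frequencies (below 1 kHz) and attenuates
#' high frequencies (above 4 kHz), each by at least `contrast_db / 2` dB on
#' average.
#'
#' @param seed RNG seed (shapes the shared resonance/ripple structure).
#' @param contrast_db total low-vs-high contrast between the two responses
#'   (> 0).
#' @param ir_length impulse-response length in samples.
#' @param n_fft design grid.
#' @param rate sampling rate in Hz.
#' @return A list of class `tf_pair` with elements `device` and `open_ear`.
#' @export
generate_transfer_function_pair <- function(seed = 1, contrast_db = 6,
                                            ir_length = 512, n_fft = 4096,
                                            rate = 44100) {
  if (!is.numeric(contrast_db) || contrast_db <= 0) {
    abort("contrast_db must be > 0.")
  }
  nh <- n_fft %/% 2 + 1
  f <- (seq_len(nh) - 1) * rate / n_fft
  fs <- pmax(f, 20)
  withr::with_seed(seed, {
    knots <- 2^seq(log2(50), log2(20000), length.out = 14)
    ripple <- stats::spline(log2(knots), stats::rnorm(14, 0, 0.8),
                            xout = log2(fs))$y
  })
  open_db <- 3 * exp(-0.5 * ((log2(fs / 2700)) / 0.6)^2) + ripple
  # shelf: +1 fully below 1 kHz, -1 fully above 4 kHz, cosine blend between
  shelf <- ifelse(fs <= 1000, 1,
                  ifelse(fs >= 4000, -1, cos(pi * log2(fs / 1000) / 2)))
  dev_db <- open_db + 1.25 * (contrast_db / 2) * shelf
  list2 <- list(
    device = minimum_phase_tf(dev_db, n_fft, ir_length, rate),
    open_ear = minimum_phase_tf(open_db, n_fft, ir_length, rate)
  )
  structure(list2, class = "tf_pair")
}

# Minimum-phase impulse response from a half-grid log-magnitude (dB) target
# via the real-cepstrum method, truncated and tapered to ir_length taps.
minimum_phase_tf <- function(mag_db_half, n_fft, ir_length, rate = 44100) {
  nh <- length(mag_db_half)
  stopifnot(nh == n_fft %/% 2 + 1)
  logmag <- c(mag_db_half, rev(mag_db_half[2:(nh - 1)])) * log(10) / 20
  cep <- Re(stats::fft(logmag, inverse = TRUE)) / n_fft
  fold <- numeric(n_fft)
  fold[1] <- cep[1]
  fold[2:(n_fft %/% 2)] <- 2 * cep[2:(n_fft %/% 2)]
  fold[n_fft %/% 2 + 1] <- cep[n_fft %/% 2 + 1]
  h <- exp(stats::fft(fold))
  ir <- Re(stats::fft(h, inverse = TRUE)) / n_fft
  ir <- ir[seq_len(ir_length)]
  ntap <- min(64, ir_length %/% 4)
  taper_idx <- seq(ir_length - ntap + 1, ir_length)
  ir[taper_idx] <- ir[taper_idx] * 0.5 * (1 + cos(pi * seq_len(ntap) / ntap))
  transfer_function(ir, rate)
}

#' Octave-band profiles of every excerpt in a corpus
#'
#' @param corpus a corpus tibble with `excerpt_id` and `wave`.
#' @param rate sampling rate in Hz.
#' @return A tibble `excerpt_id`, `center_hz`, `level_db`.
#' @export
corpus_band_profiles <- function(corpus, rate = 44100) {
  purrr::map2_dfr(corpus$excerpt_id, corpus$wave, function(id, w) {
    dplyr::mutate(octave_band_levels(w, rate), excerpt_id = id, .before = 1)
  })
}

#' Band-deviation statistics of a corpus
#'
#' Octave-band profiles are mean-centered per excerpt (removing overall
#' level), a grand mean profile is taken over the corpus (or supplied frozen),
#' and each excerpt's deviation from it is summarized per band.
#'
#' @param corpus a corpus tibble.
#' @param statistic `"mean_abs"` (mean absolute deviation over the 8 bands,
#'   default) or `"rms"` (root-mean-square over bands).
#' @param grand_mean_db optional frozen grand-mean profile (8 values).
#' @param rate sampling rate in Hz.
#' @return A tibble `excerpt_id`, `mean_dev_db`, `max_dev_db`, with the
#'   grand-mean profile attached as attribute `grand_mean_db`.
#' @export
band_deviation_stats <- function(corpus, statistic = c("mean_abs", "rms"),
                                 grand_mean_db = NULL, rate = 44100) {
  statistic <- match.arg(statistic)
  if (nrow(corpus) == 0) abort("empty corpus")
  prof <- corpus_band_profiles(corpus, rate)
  m <- matrix(prof$level_db, nrow = nrow(corpus), ncol = 8, byrow = TRUE)
  m <- m - rowMeans(m)
  if (is.null(grand_mean_db)) grand_mean_db <- colMeans(m)
  dev <- abs(sweep(m, 2, grand_mean_db))
  mean_dev <- if (statistic == "mean_abs") rowMeans(dev) else sqrt(rowMeans(dev^2))
  out <- tibble(excerpt_id = corpus$excerpt_id,
                mean_dev_db = mean_dev,
                max_dev_db = apply(dev, 1, max))
  attr(out, "grand_mean_db") <- grand_mean_db
  out
}

#' Select spectrally homogeneous excerpts from a corpus
#'
#' Keeps the excerpts whose octave-band profile deviates from the corpus
#' grand-mean profile by at most `max_mean_dev_db` on average over the eight
#' bands and at most `max_max_dev_db` in any single band. The grand mean is
#' computed over the input corpus and frozen (returned as an attribute), so
#' re-selecting with the frozen profile is idempotent.
#'
#' @param corpus a non-empty corpus tibble.
#' @param max_mean_dev_db threshold on the per-excerpt mean band deviation.
#' @param max_max_dev_db threshold on the largest single-band deviation.
#' @param statistic deviation statistic, `"mean_abs"` or `"rms"`.
#' @param grand_mean_db optional frozen grand-mean profile.
#' @param rate sampling rate in Hz.
#' @return The retained subset of `corpus`, with attributes `grand_mean_db`
#'   and `deviations` (the [band_deviation_stats()] table).
#' @export
select_homogeneous_excerpts <- function(corpus, max_mean_dev_db = 1.8,
                                        max_max_dev_db = 2.2,
                                        statistic = c("mean_abs", "rms"),
                                        grand_mean_db = NULL, rate = 44100) {
  if (nrow(corpus) == 0) abort("select_homogeneous_excerpts(): empty corpus.")
  stats_tbl <- band_deviation_stats(corpus, statistic, grand_mean_db, rate)
  keep <- stats_tbl$mean_dev_db <= max_mean_dev_db + 1e-9 &
    stats_tbl$max_dev_db <= max_max_dev_db + 1e-9
  out <- corpus[keep, ]
  attr(out, "grand_mean_db") <- attr(stats_tbl, "grand_mean_db")
  attr(out, "deviations") <- stats_tbl
  out
}
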