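white_noise <- function(n = 88200, seed = 42, peak = 0.7) {
  withr::with_seed(seed, {
    w <- stats::rnorm(n)
    w / max(abs(w)) * peak
  })
}

test_that("octave levels of white noise rise ~3 dB per octave", {
  lv <- octave_band_levels(white_noise())
  expect_true(all(abs(diff(lv$level_db) - 10 * log10(2)) < 1))
})

test_that("a pure 1 kHz tone excites only the 1 kHz band", {
  n <- 88200
  k <- round(1000 * n / 44100)
  tone <- 0.5 * sin(2 * pi * k * (0:(n - 1)) / n)
  lv <- octave_band_levels(tone)
  expect_gt(lv$level_db[4] - max(lv$level_db[-4]), 20)
  expect_identical(lv, octave_band_levels(tone))
  expect_error(octave_band_levels(numeric(100)), "non-silent")
})

test_that("slope 0 is flat through the analysis-synthesis chain", {
  w <- white_noise()
  d <- octave_band_levels(apply_spectral_slope(w, 0))$level_db -
    octave_band_levels(w)$level_db
  expect_true(all(abs(d) < 1))
})

test_that("slope gains tilt band levels by slope x log2(f/pivot)", {
  w <- white_noise(seed = 3)
  l0 <- octave_band_levels(apply_spectral_slope(w, 0))$level_db
  l2 <- octave_band_levels(apply_spectral_slope(w, 2))$level_db
  # between 125 Hz and 8 kHz centers: 2 dB/oct * 6 octaves = 12 dB
  expect_lt(abs((l2[7] - l0[7]) - (l2[1] - l0[1]) - 12), 1.5)
  # the 16 kHz band is held at the 8 kHz gain by default
  expect_lt(abs((l2[8] - l0[8]) - (l2[7] - l0[7])), 1)
  # ... but slopes on with the extended region
  l2x <- octave_band_levels(apply_spectral_slope(w, 2, extend_to_16k = TRUE))$level_db
  expect_gt((l2x[8] - l0[8]) - (l2x[7] - l0[7]), 1)
  expect_error(apply_spectral_slope(w, 7), "max_abs_slope")
})

test_that("opposite slopes approximately invert through the filterbank", {
  w <- white_noise(seed = 5)
  base <- octave_band_levels(apply_spectral_slope(w, 0))$level_db
  comp <- octave_band_levels(
    apply_spectral_slope(apply_spectral_slope(w, 1), -1))$level_db
  expect_true(all(abs(comp - base) < 1.5))
})

test_that("slope filtering is level-linear", {
  w <- white_noise(44100, seed = 8)
  expect_equal(apply_spectral_slope(0.3 * w, 1.5), 0.3 * apply_spectral_slope(w, 1.5),
               tolerance = 1e-12)
})

test_that("morph endpoints reproduce the input transfer functions exactly", {
  tfp <- tf_pair_6()
  for (m in c(0, 1)) {
    ref <- if (m == 0) tfp$device else tfp$open_ear
    out <- morph_transfer_functions(tfp$device, tfp$open_ear, m)
    expect_lt(max(abs(out$ir[seq_along(ref$ir)] - ref$ir)), 1e-9)
    expect_lt(max(abs(out$ir[-seq_along(ref$ir)])), 1e-9)
  }
})

test_that("morphing flat responses inter- and extrapolates in dB", {
  ta <- transfer_function(c(1, numeric(63)))
  tb <- transfer_function(c(10^(-6 / 20), numeric(63)))
  mag_db <- function(tf) 20 * log10(Mod(tf_frequency_response(tf, 128)))
  expect_equal(unname(mag_db(morph_transfer_functions(ta, tb, 0.5))),
               rep(-3, 128), tolerance = 1e-9)
  expect_equal(unname(mag_db(morph_transfer_functions(ta, tb, 1.5))),
               rep(-9, 128), tolerance = 1e-9)
})

test_that("morphing is closed under affine combination", {
  tfp <- generate_transfer_function_pair(seed = 9, contrast_db = 8,
                                         ir_length = 128, n_fft = 1024)
  a <- tfp$device; b <- tfp$open_ear
  c1 <- morph_transfer_functions(a, b, 0.2, n_fft = 1024)
  c2 <- morph_transfer_functions(a, b, 0.9, n_fft = 1024)
  for (t in c(0.3, 0.75)) {
    direct <- morph_transfer_functions(a, b, (1 - t) * 0.2 + t * 0.9,
                                       n_fft = 1024)
    nested <- morph_transfer_functions(c1, c2, t, n_fft = 1024)
    expect_lt(max(abs(direct$ir - nested$ir[seq_along(direct$ir)])), 1e-6)
  }
})

test_that("morphing rejects grid mismatch and zero-magnitude bins", {
  ta <- transfer_function(c(1, numeric(31)), rate = 44100)
  tb <- transfer_function(c(1, numeric(31)), rate = 48000)
  expect_error(morph_transfer_functions(ta, tb, 0.5), "grid mismatch")
  tz <- transfer_function(c(1, 1))  # H = 0 at Nyquist
  expect_error(morph_transfer_functions(tz, ta, 0.5, n_fft = 32), "bin")
})

test_that("convolution is exact for (delayed) unit impulses", {
  x <- white_noise(4410, seed = 2, peak = 0.5)
  expect_equal(apply_transfer_function(x, transfer_function(c(1, numeric(9)))),
               x, tolerance = 1e-12)
  y <- apply_transfer_function(x, transfer_function(c(numeric(5), 1)))
  expect_equal(y, c(numeric(5), x[1:(4410 - 5)]), tolerance = 1e-12)
  expect_message(
    apply_transfer_function(x, transfer_function(c(4, numeric(3)))),
    "re-normalized")
})

test_that("band levels after a known low-pass match its band-averaged gain", {
  w <- white_noise(seed = 12)
  # min-phase low-pass: flat to 1 kHz, -30 dB by 8 kHz
  n_fft <- 4096
  f <- (seq_len(n_fft / 2 + 1) - 1) * 44100 / n_fft
  mag_db <- pmax(-30, pmin(0, -30 * log2(pmax(f, 1) / 1000) / 3))
  tf <- brightadapt:::minimum_phase_tf(mag_db, n_fft, 1024)
  y <- suppressMessages(apply_transfer_function(w, tf))
  meas <- octave_band_levels(y)$level_db - octave_band_levels(w)$level_db

  # oracle: power-average |H|^2 over each octave band's filter response
  h2 <- Mod(tf_frequency_response(tf, n_fft))[seq_len(n_fft / 2 + 1)]^2
  edges <- brightadapt:::octave_band_edges(44100)
  pred <- vapply(seq_len(8), function(b) {
    g <- brightadapt:::butter_bandpass_response(f, edges$lo_hz[b], edges$hi_hz[b])
    10 * log10(sum(h2 * g^2) / sum(g^2))
  }, numeric(1))
  expect_true(all(abs(meas - pred) < 1.5))
})
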