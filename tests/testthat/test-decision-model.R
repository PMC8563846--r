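test_that("parameter validation enforces the admissible ranges", {
  expect_s3_class(decision_params(), "decision_params")
  expect_error(decision_params(alpha = 1.2))
  expect_error(decision_params(integration_length_s = 0))
  expect_error(decision_params(lapse_rate = 0.5))
  expect_error(decision_params(alpha = 0.5,
                               lt_mode = "unprocessed_domain_median"),
               "lt_reference_hz")
})

test_that("the short-term window walks back by stimulus duration", {
  h <- tibble::tibble(sc_hz = (1:10) * 100, duration_s = rep(2, 10))
  expect_equal(st_window(h, 10, 4), c(800, 900))
  expect_equal(st_window(h, 5, 0.5), 400)
  h2 <- h
  h2$duration_s[9] <- 8  # long adaptor right before trial 10
  expect_equal(st_window(h2, 10, 4), 900)
  expect_error(st_window(h, 1, 4), "no history")
})

test_that("the criterion mixes ST and LT medians per Eq.-style weighting", {
  h <- tibble::tibble(sc_hz = c(1000, 3000, 2000, 2500, 1500),
                      duration_s = rep(2, 5))
  # alpha = 1, single-element window
  p1 <- decision_params(alpha = 1, integration_length_s = 1, lapse_rate = 0)
  expect_equal(decision_criterion(h, 2, p1), 1000)
  # alpha = 0: the LT median regardless of trial index
  p0 <- decision_params(alpha = 0, lapse_rate = 0)
  for (n in 2:5) expect_equal(decision_criterion(h, n, p0), stats::median(h$sc_hz))
  p0u <- decision_params(alpha = 0, lapse_rate = 0,
                         lt_mode = "unprocessed_domain_median",
                         lt_reference_hz = 1234)
  expect_equal(decision_criterion(h, 3, p0u), 1234)
  # alpha = 0.5: arithmetic mean of the two terms
  ph <- decision_params(alpha = 0.5, integration_length_s = 1, lapse_rate = 0,
                        lt_mode = "unprocessed_domain_median",
                        lt_reference_hz = 2000)
  expect_equal(decision_criterion(h, 2, ph), (1000 + 2000) / 2)
})

test_that("criterion_series agrees with per-trial st_window medians", {
  h <- tibble::tibble(
    sc_hz = withr::with_seed(6, stats::runif(30, 500, 4000)),
    duration_s = withr::with_seed(7, sample(c(1, 2, 4, 8), 30, replace = TRUE)))
  for (L in c(0.5, 4, 16, 64)) {
    p <- decision_params(alpha = 1, integration_length_s = L, lapse_rate = 0)
    crit <- brightadapt:::criterion_series(h$sc_hz, h$duration_s, p)
    expect_true(is.na(crit[1]))
    for (n in c(2, 3, 15, 30)) {
      expect_equal(crit[n], stats::median(st_window(h, n, L)))
    }
  }
})

test_that("responses are strict-threshold with dull ties and a lapse flip", {
  expect_equal(respond(1500, 1000, lapse_rate = 0)$response, "bright")
  expect_equal(respond(1000, 1000, lapse_rate = 0)$response, "dull")
  expect_equal(respond(999.9, 1000, lapse_rate = 0)$response, "dull")
  r <- respond(rep(2000, 1e5), 1000, lapse_rate = 0.05, seed = 42)
  expect_lt(abs(mean(r$response == "dull") - 0.05), 0.005)
  expect_true(all(r$lapsed == (r$response == "dull")))
})

test_that("virtual participants respond deterministically given a seed", {
  des <- toy_design(12)
  sc <- seq(1000, 2100, by = 100)
  tab <- toy_sc_table(des, sc)
  p <- decision_params(alpha = 1, integration_length_s = 16, lapse_rate = 0)
  r <- run_virtual_participant(des, tab, p, seed = 1)
  # strictly increasing SCs: everything after trial 1 is bright
  expect_equal(r$response, c("none", rep("bright", 11)))
  rc <- run_virtual_participant(des, toy_sc_table(des, rep(1500, 12)), p, seed = 1)
  expect_equal(rc$response, c("none", rep("dull", 11)))  # ties are dull
  p5 <- decision_params(alpha = 1, integration_length_s = 16, lapse_rate = 0.05)
  expect_identical(run_virtual_participant(des, tab, p5, seed = 9),
                   run_virtual_participant(des, tab, p5, seed = 9))
  bad <- tab[-3, ]
  expect_error(run_virtual_participant(des, bad, p, seed = 1), "trial 3")
})

test_that("first-trial policy skips or answers at chance", {
  des <- toy_design(5)
  tab <- toy_sc_table(des, c(1500, 1000, 2000, 1200, 1800))
  pskip <- decision_params(alpha = 1, lapse_rate = 0)
  r <- run_virtual_participant(des, tab, pskip, seed = 2)
  expect_equal(r$response[1], "none")
  expect_true(is.na(r$lapsed[1]))
  pch <- decision_params(alpha = 1, lapse_rate = 0, first_trial_policy = "chance")
  r2 <- run_virtual_participant(des, tab, pch, seed = 2)
  expect_true(r2$response[1] %in% c("bright", "dull"))
  # with a pure LT criterion the first trial is answerable
  plt <- decision_params(alpha = 0, lapse_rate = 0)
  r3 <- run_virtual_participant(des, tab, plt, seed = 2)
  expect_true(r3$response[1] %in% c("bright", "dull"))
})

test_that("the model collapses: alpha=1 ignores the LT mode, alpha=0 ignores L", {
  des <- toy_design(20)
  tab <- toy_sc_table(des, withr::with_seed(8, stats::runif(20, 800, 3000)))
  r_a <- run_virtual_participant(des, tab,
    decision_params(alpha = 1, integration_length_s = 8, lapse_rate = 0.05,
                    lt_mode = "session_median"), seed = 3)
  r_b <- run_virtual_participant(des, tab,
    decision_params(alpha = 1, integration_length_s = 8, lapse_rate = 0.05,
                    lt_mode = "unprocessed_domain_median",
                    lt_reference_hz = 99999), seed = 3)
  expect_identical(r_a$response, r_b$response)
  r_c <- run_virtual_participant(des, tab,
    decision_params(alpha = 0, integration_length_s = 4, lapse_rate = 0.05),
    seed = 3)
  r_d <- run_virtual_participant(des, tab,
    decision_params(alpha = 0, integration_length_s = 256, lapse_rate = 0.05),
    seed = 3)
  expect_identical(r_c$response, r_d$response)
})

test_that("cohort simulation is reproducible and labels participants", {
  des_fn <- function(seed) toy_design(9)
  tab <- toy_sc_table(toy_design(9), withr::with_seed(5, stats::runif(9, 1000, 2000)))
  p <- decision_params(alpha = 1, lapse_rate = 0.05)
  r1 <- simulate_participants(des_fn, tab, p, n_participants = 4, seed = 11)
  r2 <- simulate_participants(des_fn, tab, p, n_participants = 4, seed = 11)
  expect_identical(r1, r2)
  expect_equal(dplyr::n_distinct(r1$participant), 4)
  expect_equal(nrow(r1), 36)
})
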