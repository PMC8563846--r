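# compact builder for hand-made response tables
resp_tbl <- function(participant, coloration, response,
                     context = "none", role = "target", session = "s1") {
  tibble::tibble(
    participant = participant, session_id = session, experiment = "exp1",
    context = context, domain = "music", index_n = seq_along(coloration),
    role = role, coloration = coloration, duration_s = 2,
    excerpt_id = sprintf("e%03d", seq_along(coloration)),
    speaker_id = NA_character_, sc_hz = NA_real_, criterion_hz = NA_real_,
    response = response, lapsed = FALSE)
}

test_that("degenerate all-bright responses aggregate to p = 1 everywhere", {
  r <- dplyr::bind_rows(
    resp_tbl("p1", rep(c(-1, 1), 10), rep("bright", 20)),
    resp_tbl("p2", rep(c(1, -1), 10), rep("bright", 20)))
  a <- aggregate_conditions(r, "exp1", n_boot = 50, seed = 1)
  expect_true(all(a$p_bright[a$n_trials > 0] == 1))
  expect_true(all(a$ci_lo[a$n_trials > 0] == 1 & a$ci_hi[a$n_trials > 0] == 1))
})

test_that("condition cells match a hand enumeration on a 6-trial session", {
  # slopes: 1, -2, 0.5, -0.5, 2, 0; trial 1 has no classified predecessor
  r <- resp_tbl("p1", c(1, -2, 0.5, -0.5, 2, 0),
                c("bright", "dull", "bright", "dull", "bright", "dull"))
  a <- aggregate_conditions(r, "exp1", n_boot = 0)
  cell <- function(lv, pc) {
    a[a$coloration == lv & a$prev_class == pc, ]
  }
  # trial 2 (slope -2, prev 1 > 0 -> prev_bright, dull)
  expect_equal(cell(-2, "prev_bright")$p_bright, 0)
  expect_equal(cell(-2, "prev_bright")$n_trials, 1L)
  # trial 3 (slope 0.5, prev -2 -> prev_dull, bright)
  expect_equal(cell(0.5, "prev_dull")$p_bright, 1)
  # trial 4 (slope -0.5, prev 0.5 -> prev_bright, dull)
  expect_equal(cell(-0.5, "prev_bright")$p_bright, 0)
  # trial 5 (slope 2, prev -0.5 -> prev_dull, bright)
  expect_equal(cell(2, "prev_dull")$p_bright, 1)
  # trial 6 (slope 0, prev 2 -> prev_bright, dull)
  expect_equal(cell(0, "prev_bright")$p_bright, 0)
  # empty grid cells are reported, flagged by n_trials = 0
  expect_equal(cell(-2, "prev_dull")$n_trials, 0L)
  expect_true(is.na(cell(-2, "prev_dull")$p_bright))
  # the relative previous-trial variant reclassifies trial 5 (prev smaller)
  a_rel <- aggregate_conditions(r, "exp1", n_boot = 0, prev_variant = "relative")
  expect_equal(a_rel[a_rel$coloration == 2 & a_rel$prev_class == "prev_dull", ]$n_trials, 1L)
})

test_that("aggregation is invariant to participant order and bootstrap brackets p", {
  r <- dplyr::bind_rows(
    resp_tbl("p1", rep(c(-1, 1), 15), rep(c("dull", "bright"), 15)),
    resp_tbl("p2", rep(c(-1, 1), 15), rep(c("dull", "dull"), 15)),
    resp_tbl("p3", rep(c(-1, 1), 15), rep(c("bright", "bright"), 15)))
  a1 <- aggregate_conditions(r, "exp1", n_boot = 200, seed = 3)
  a2 <- aggregate_conditions(r[sample(nrow(r)), ] |>
                               dplyr::arrange(match(participant, c("p3", "p1", "p2")),
                                              index_n),
                             "exp1", n_boot = 200, seed = 3)
  expect_equal(a1, a2)
  ok <- a1$n_trials > 0
  expect_true(all(a1$ci_lo[ok] <= a1$p_bright[ok] + 1e-12 &
                    a1$ci_hi[ok] >= a1$p_bright[ok] - 1e-12))
})

test_that("inclusion thresholds behave exactly as printed at the boundaries", {
  pp <- function(p_lo, p_hi) tibble::tibble(
    participant = "p1", session_id = "s1", context = "none",
    coloration = c(-2, 2), p_bright = c(p_lo, p_hi), n_trials = 50)
  expect_true(apply_inclusion_criterion(pp(0.1, 0.9), "exp1")$retained)
  expect_false(apply_inclusion_criterion(pp(0.30, 0.69), "exp1")$retained)
  expect_true(apply_inclusion_criterion(pp(0.30, 0.70), "exp1")$retained)
  # exp2: 20-point threshold over -1..+1, boundary inclusive
  pp2 <- pp(0.40, 0.60); pp2$coloration <- c(-1, 1)
  expect_true(apply_inclusion_criterion(pp2, "exp2")$retained)
  pp3 <- pp(0.40, 0.59); pp3$coloration <- c(-1, 1)
  expect_false(apply_inclusion_criterion(pp3, "exp2")$retained)
  # a participant must clear the bar in every session
  two <- dplyr::bind_rows(pp(0.1, 0.9),
                          dplyr::mutate(pp(0.3, 0.5), session_id = "s2"))
  expect_false(apply_inclusion_criterion(two, "exp3")$retained)
  expect_error(apply_inclusion_criterion(pp(0.5, 0.5)[1, ], "exp1"),
               "extreme levels")
})

test_that("adaptation contrast reproduces the printed arithmetic", {
  s <- tibble::tibble(
    experiment = "exp3", context = c("shift_minus_1", "shift_plus_1"),
    coloration = 0, prev_class = "all", p_bright = c(0.66, 0.31),
    n_trials = 100L)
  expect_equal(adaptation_contrast(s, 0, by = "context"), 35, tolerance = 1e-9)
  s2 <- s; s2$p_bright <- c(0.4, 0.4)
  expect_equal(adaptation_contrast(s2, 0, by = "context"), 0)
  s3 <- s; s3$p_bright <- c(1, 0)
  expect_equal(adaptation_contrast(s3, 0, by = "context"), 100)
  expect_error(adaptation_contrast(s, 7), "no cells")
})

test_that("trajectories smooth with a centered moving average", {
  step <- resp_tbl("p1", rep(0, 40), rep(c("dull", "bright"), each = 20))
  tr <- response_trajectory(step, shared_levels = 0, window = 10)
  raw <- as.numeric(tr$p_raw)
  # oracle: explicit centered window mean (4 back, 5 forward)
  for (i in c(5, 16, 20, 25, 35)) {
    expect_equal(tr$p_smooth[i], mean(raw[(i - 4):(i + 5)]))
  }
  expect_true(all(is.na(tr$p_smooth[1:4])))
  const <- resp_tbl("p1", rep(0, 30), rep("bright", 30))
  tc <- response_trajectory(const, 0, window = 10)
  expect_equal(tc$p_smooth[!is.na(tc$p_smooth)], rep(1, 21), tolerance = 1e-12)
  t1 <- response_trajectory(step, 0, window = 1)
  expect_equal(t1$p_smooth, raw)
  expect_error(response_trajectory(step[1:5, ], 0, window = 10), "at least")
})

test_that("the logistic summarizer is calibrated under a null previous-trial effect", {
  corp <- fake_corpus(360)
  covered <- 0
  withr::with_seed(42, {
    for (rep in 1:100) {
      d <- design_exp1(corp, seed = sample.int(1e6, 1))
      pr <- stats::plogis(1.2 * d$coloration)
      d$response <- ifelse(stats::runif(350) < pr, "bright", "dull")
      d$participant <- "p1"
      d$lapsed <- FALSE
      fit <- fit_logistic_context_model(d, "exp1")
      ci <- fit$table[fit$table$term == "prev_ec", ]
      if (ci$conf_low <= 0 && ci$conf_high >= 0) covered <- covered + 1
    }
  })
  expect_gte(covered, 90)
})

test_that("perfectly level-determined responses raise the separation flag", {
  corp <- fake_corpus(360)
  d <- design_exp1(corp, seed = 77)
  d$response <- ifelse(d$coloration > 0, "bright", "dull")
  d$participant <- "p1"
  fit <- fit_logistic_context_model(d, "exp1")
  expect_true(fit$separated)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(is.finite(glance(fit)$deviance))
})

test_that("pooled RMS decomposes over experiments by cell counts", {
  withr::with_seed(9, {
    mp <- stats::runif(30); rp <- stats::runif(30)
    ex <- rep(c("exp1", "exp2", "exp3"), times = c(14, 6, 10))
  })
  total <- pooled_rms(mp, rp)
  per <- tapply((mp - rp)^2, ex, mean)
  n <- tapply(mp, ex, length)
  expect_equal(total, sqrt(sum(per * n) / sum(n)), tolerance = 1e-12)
  expect_equal(pooled_rms(mp, rp, ex, weighting = "experiment"),
               sqrt(mean(per)), tolerance = 1e-12)
  # invariance to cell ordering
  o <- sample(30)
  expect_equal(pooled_rms(mp[o], rp[o]), total)
})

test_that("evaluating a model against its own output gives zero RMS and r = 1", {
  suite1 <- suite_13()["exp1"]
  p <- decision_params(alpha = 1, integration_length_s = 16)
  ref <- simulate_reference(suite1, p, n_participants = 5, seed = 9)
  ev <- evaluate_model(ref, suite1, "st", L_grid = 16, n_participants = 5,
                       seed = 9)
  expect_equal(ev$rms_by_L$rms, 0)
  expect_equal(ev$pearson_r, 1)
  # a reference cell the model cannot produce is reported, not dropped
  ref_bad <- dplyr::bind_rows(ref, dplyr::mutate(ref[1, ], coloration = 99,
                                                 p_bright = 0.5))
  expect_error(evaluate_model(ref_bad, suite1, "st", L_grid = 16,
                              n_participants = 5, seed = 9), "missing")
})

test_that("the LT model's error profile is independent of integration length", {
  suite1 <- suite_13()["exp1"]
  ref <- simulate_reference(suite1,
                            decision_params(alpha = 0, lapse_rate = 0.05),
                            n_participants = 5, seed = 21)
  ev <- evaluate_model(ref, suite1, "lt", L_grid = c(4, 16, 64),
                       n_participants = 5, seed = 22)
  expect_equal(diff(range(ev$rms_by_L$rms)), 0)
})
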