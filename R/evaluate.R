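# Previous-trial context class per experiment convention:
#  exp1: sign of the previous slope ("absolute") or previous vs current slope
#        ("relative"); exp2: slope of the preceding adaptor; exp3/exp4:
#        previous coloration above/below the session's mean level.
classify_previous <- function(responses, experiment,
                              prev_variant = c("absolute", "relative")) {
  prev_variant <- match.arg(prev_variant)
  grp <- dplyr::group_by(responses, .data$participant, .data$session_id)
  out <- dplyr::mutate(grp, .prev = dplyr::lag(.data$coloration))
  out <- dplyr::ungroup(out)
  if (experiment == "exp1") {
    if (prev_variant == "absolute") {
      cls <- dplyr::case_when(out$.prev > 0 ~ "prev_bright",
                              out$.prev < 0 ~ "prev_dull")
    } else {
      cls <- dplyr::case_when(out$.prev > out$coloration ~ "prev_bright",
                              out$.prev < out$coloration ~ "prev_dull")
    }
  } else if (experiment == "exp2") {
    cls <- dplyr::case_when(out$.prev > 0 ~ "prev_bright",
                            out$.prev < 0 ~ "prev_dull")
  } else {
    ses_mean <- stats::ave(out$coloration,
                           paste(out$participant, out$session_id),
                           FUN = function(x) mean(unique(x)))
    cls <- dplyr::case_when(out$.prev > ses_mean ~ "prev_bright",
                            out$.prev < ses_mean ~ "prev_dull")
  }
  out$prev_class <- cls
  out$.prev <- NULL
  out
}

#' Aggregate responses into condition cells
#'
#' Computes the proportion of *bright* responses per condition cell
#' (coloration level x previous-trial class x context), averaging
#' participant-level proportions, with percentile bootstrap confidence
#' intervals over participants. First trials, lapse-platform `"none"`
#' responses, trials without a classified predecessor, and (for the hidden
#' adaptor experiment) adaptor trials are excluded. Cells of the full grid
#' with no data are reported with `n_trials = 0`, not dropped.
#'
#' @param responses a response tibble from [simulate_participants()] (or
#'   human data in the same layout).
#' @param experiment `"exp1"`, `"exp2"`, `"exp3"` or `"exp4"`.
#' @param n_boot bootstrap resamples over participants (0 disables CIs).
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @param prev_variant previous-trial classification for exp1, `"absolute"`
#'   (sign of previous slope) or `"relative"` (previous vs current slope).
#' @return A `condition_summary` tibble with `experiment`, `context`,
#'   `coloration`, `prev_class`, `p_bright`, `n_trials`, `n_participants`,
#'   `ci_lo`, `ci_hi`.
#' @export
aggregate_conditions <- function(responses, experiment, n_boot = 2000,
                                 conf = 0.95, seed = 1,
                                 prev_variant = c("absolute", "relative")) {
  cls <- classify_previous(responses, experiment, match.arg(prev_variant))
  keep <- cls$response %in% c("bright", "dull") & !is.na(cls$prev_class)
  if (experiment == "exp2") keep <- keep & cls$role == "target"
  dat <- cls[keep, ]
  per <- dplyr::summarise(
    dplyr::group_by(dat, .data$participant, .data$context, .data$coloration,
                    .data$prev_class),
    p = mean(.data$response == "bright"), n = dplyr::n(), .groups = "drop")
  per <- tidyr::complete(per, !!rlang::sym("participant"),
                         tidyr::nesting(!!rlang::sym("context"),
                                        !!rlang::sym("coloration")),
                         !!rlang::sym("prev_class"),
                         fill = list(n = 0L))
  cells <- dplyr::summarise(
    dplyr::group_by(per, .data$context, .data$coloration, .data$prev_class),
    p_bright = mean(.data$p, na.rm = TRUE),
    n_trials = sum(.data$n),
    n_participants = sum(!is.na(.data$p)),
    .groups = "drop")
  cells$p_bright[cells$n_trials == 0] <- NA_real_
  cells <- dplyr::mutate(cells, ci_lo = NA_real_, ci_hi = NA_real_)
  if (n_boot > 0) {
    wide <- tidyr::pivot_wider(
      per, id_cols = "participant",
      names_from = c("context", "coloration", "prev_class"),
      values_from = "p", names_sep = "\r")
    m <- as.matrix(wide[, -1])
    keys <- do.call(rbind, strsplit(colnames(m), "\r", fixed = TRUE))
    qs <- withr::with_seed(seed, {
      boot <- matrix(NA_real_, n_boot, ncol(m))
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nrow(m), replace = TRUE)
        boot[b, ] <- colMeans(m[idx, , drop = FALSE], na.rm = TRUE)
      }
      apply(boot, 2, stats::quantile,
            probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    })
    ci <- tibble(context = keys[, 1],
                 coloration = as.numeric(keys[, 2]),
                 prev_class = keys[, 3],
                 ci_lo = qs[1, ], ci_hi = qs[2, ])
    cells$ci_lo <- NULL; cells$ci_hi <- NULL
    cells <- dplyr::left_join(cells, ci,
                              by = c("context", "coloration", "prev_class"))
  }
  out <- dplyr::mutate(cells, experiment = experiment, .before = 1)
  out <- dplyr::arrange(out, .data$context, .data$coloration, .data$prev_class)
  class(out) <- c("condition_summary", class(out))
  out
}

#' Per-participant proportion of bright responses per level
#'
#' The participant-level summaries on which the inclusion criterion operates.
#' @inheritParams aggregate_conditions
#' @return A tibble `participant`, `session_id`, `context`, `coloration`,
#'   `p_bright`, `n_trials`.
#' @export
participant_level_props <- function(responses, experiment) {
  dat <- responses[responses$response %in% c("bright", "dull"), ]
  if (experiment == "exp2") dat <- dat[dat$role == "target", ]
  dplyr::summarise(
    dplyr::group_by(dat, .data$participant, .data$session_id, .data$context,
                    .data$coloration),
    p_bright = mean(.data$response == "bright"), n_trials = dplyr::n(),
    .groups = "drop")
}

#' Apply the participant inclusion criterion
#'
#' A participant is retained when, in every session, the gain in proportion
#' bright between the two most extreme coloration levels reaches the
#' experiment's threshold: 40 percentage points over the 4 dB/oct slope span
#' of the -2..+2 (and shifted) slope experiments and the morph experiment's
#' extreme levels, 20 points over the -1..+1 span of the hidden-adaptor
#' experiment. Equality retains (the criterion excludes *smaller* gains).
#'
#' @param per_participant a tibble from [participant_level_props()] (or
#'   equivalent: `participant`, `session_id`, `coloration`, `p_bright`).
#' @param experiment experiment label (sets the default threshold).
#' @param threshold_pp override threshold in percentage points.
#' @return A tibble `participant`, `gain_pp` (smallest session gain, in
#'   percentage points), `retained`.
#' @export
apply_inclusion_criterion <- function(per_participant, experiment,
                                      threshold_pp = NULL) {
  if (is.null(threshold_pp)) {
    threshold_pp <- if (experiment == "exp2") 20 else 40
  }
  gains <- dplyr::summarise(
    dplyr::group_by(per_participant, .data$participant, .data$session_id),
    gain = {
      lv <- .data$coloration
      if (length(unique(lv)) < 2) {
        abort("inclusion criterion needs both extreme levels per session.")
      }
      100 * (.data$p_bright[which.max(lv)] - .data$p_bright[which.min(lv)])
    },
    .groups = "drop")
  out <- dplyr::summarise(dplyr::group_by(gains, .data$participant),
                          gain_pp = min(.data$gain), .groups = "drop")
  out$retained <- out$gain_pp >= threshold_pp - 1e-9
  out
}

#' Contrastive adaptation (or context) effect at a level
#'
#' The percentage-point difference in proportion bright between the
#' dull-context cell and the bright-context cell at a coloration level. The
#' cells are split by `prev_class` when both previous-trial classes are
#' present at the level, otherwise by global `context` (where the
#' down-shifted / device grid counts as the dull context).
#'
#' @param summaries a `condition_summary` tibble.
#' @param level the coloration level at which to compare.
#' @param by `"auto"`, `"prev_class"` or `"context"`.
#' @return Difference in percentage points.
#' @export
adaptation_contrast <- function(summaries, level,
                                by = c("auto", "prev_class", "context")) {
  by <- match.arg(by)
  s <- summaries[abs(summaries$coloration - level) < 1e-9 &
                   !is.na(summaries$p_bright), ]
  if (nrow(s) == 0) abort(sprintf("no cells at level %s.", format(level)))
  if (by == "auto") {
    by <- if (length(unique(s$prev_class)) >= 2) "prev_class" else "context"
  }
  if (by == "prev_class") {
    dull <- mean(s$p_bright[s$prev_class == "prev_dull"])
    bright <- mean(s$p_bright[s$prev_class == "prev_bright"])
  } else {
    dull_ctx <- c("shift_minus_1", "device_context")
    dull <- mean(s$p_bright[s$context %in% dull_ctx])
    bright <- mean(s$p_bright[!s$context %in% dull_ctx])
  }
  if (!is.finite(dull) || !is.finite(bright)) {
    abort("missing cell: both context classes are needed at this level.")
  }
  100 * (dull - bright)
}

#' Smoothed response trajectory over trials
#'
#' Averages the bright-response indicator over participants per trial index
#' and context, restricted to the shared coloration levels, and smooths with
#' a centered `window`-point moving average (for plotting on a log trial
#' axis). Incomplete windows at the edges yield `NA`.
#'
#' @param responses a response tibble.
#' @param shared_levels coloration levels common to the contexts.
#' @param window moving-average length in trials.
#' @return A tibble `context`, `index_n`, `p_raw`, `p_smooth`.
#' @export
response_trajectory <- function(responses, shared_levels, window = 10) {
  keep <- responses$response %in% c("bright", "dull") &
    vapply(responses$coloration,
           function(x) any(abs(x - shared_levels) < 1e-9), logical(1))
  dat <- responses[keep, ]
  traj <- dplyr::summarise(
    dplyr::group_by(dat, .data$context, .data$index_n),
    p_raw = mean(.data$response == "bright"), .groups = "drop")
  traj <- dplyr::arrange(traj, .data$context, .data$index_n)
  smooth_one <- function(x) {
    if (length(x) < window) {
      abort(sprintf("need at least %d trials at the shared levels.", window))
    }
    if (window == 1) return(x)
    as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  }
  dplyr::mutate(dplyr::group_by(traj, .data$context),
                p_smooth = smooth_one(.data$p_raw)) |>
    dplyr::ungroup()
}

#' Fixed-effects logistic summary of context effects
#'
#' Binomial regression (logit link) of the bright response on the coloration
#' level, the effects-coded previous-trial class (+1 previous-bright, -1
#' previous-dull) and, when two global contexts are present, the
#' effects-coded context (+1 up-shifted / open-ear). A fixed-effects
#' summarizer for sign and direction checks on simulated data; it estimates
#' no random effects.
#'
#' @inheritParams aggregate_conditions
#' @return An object of class `context_logit` with a broom-style coefficient
#'   table (Wald 95% intervals) and a separation flag.
#' @export
fit_logistic_context_model <- function(responses, experiment,
                                       prev_variant = c("absolute",
                                                        "relative")) {
  cls <- classify_previous(responses, experiment, match.arg(prev_variant))
  keep <- cls$response %in% c("bright", "dull") & !is.na(cls$prev_class)
  if (experiment == "exp2") keep <- keep & cls$role == "target"
  dat <- cls[keep, ]
  if (length(unique(dat$coloration)) < 2 ||
      length(unique(dat$prev_class)) < 2) {
    abort("need at least two levels of coloration and previous-trial class.")
  }
  df <- data.frame(
    bright = dat$response == "bright",
    level = dat$coloration,
    prev_ec = ifelse(dat$prev_class == "prev_bright", 1, -1)
  )
  form <- bright ~ level + prev_ec
  if (length(unique(dat$context)) >= 2) {
    df$context_ec <- ifelse(
      dat$context %in% c("shift_plus_1", "openear_context"), 1, -1)
    form <- bright ~ level + prev_ec + context_ec
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  separated <- separated || any(abs(stats::coef(fit)) > 15)
  co <- summary(fit)$coefficients
  tab <- tibble(
    term = rownames(co),
    estimate = co[, 1],
    std_error = co[, 2],
    conf_low = co[, 1] - stats::qnorm(0.975) * co[, 2],
    conf_high = co[, 1] + stats::qnorm(0.975) * co[, 2],
    statistic = co[, 3],
    p_value = co[, 4]
  )
  structure(list(fit = fit, table = tab, separated = separated,
                 n = nrow(df), experiment = experiment),
            class = "context_logit")
}

#' @export
print.context_logit <- function(x, ...) {
  cat(sprintf("<context_logit: %s, n = %d%s>\n", x$experiment, x$n,
              if (x$separated) ", SEPARATION FLAGGED" else ""))
  print(x$table)
  invisible(x)
}

#' Pooled RMS error between model and reference cells
#'
#' @param model_p,ref_p matched cell proportions.
#' @param experiment optional experiment labels for per-experiment weighting.
#' @param weighting `"none"` (unweighted over all cells, default) or
#'   `"experiment"` (equal weight per experiment).
#' @export
pooled_rms <- function(model_p, ref_p, experiment = NULL,
                       weighting = c("none", "experiment")) {
  weighting <- match.arg(weighting)
  sq <- (model_p - ref_p)^2
  if (weighting == "none" || is.null(experiment)) return(sqrt(mean(sq)))
  sqrt(mean(tapply(sq, experiment, mean)))
}

# One full pass: simulate every experiment of a suite under one parameter
# setting and aggregate to condition cells.
simulate_suite_cells <- function(suite, params, n_participants, seed,
                                 participant_seeds = NULL,
                                 prev_variant = "absolute") {
  cells <- lapply(suite, function(exp) {
    p <- params
    if (p$lt_mode == "unprocessed_domain_median") {
      p$lt_reference_hz <- exp$lt_reference_hz
    }
    resp <- simulate_participants(exp$design_fn, exp$sc_table, p,
                                  n_participants, seed,
                                  participant_seeds = participant_seeds)
    aggregate_conditions(resp, exp$experiment, n_boot = 0,
                         prev_variant = prev_variant)
  })
  dplyr::bind_rows(cells)
}

#' Simulate reference condition cells from a known model
#'
#' Convenience wrapper producing a "pseudo-empirical" reference: the
#' condition-cell summary of a cohort simulated under known parameters.
#'
#' @param suite an experiment suite: a list whose elements carry
#'   `experiment`, `design_fn(seed)`, `sc_table` and (for the long-term
#'   criterion) `lt_reference_hz`.
#' @param params a [decision_params()] object.
#' @param n_participants cohort size.
#' @param seed master seed.
#' @return A `condition_summary` tibble over all suite experiments.
#' @export
simulate_reference <- function(suite, params, n_participants = 50, seed = 1) {
  simulate_suite_cells(suite, params, n_participants, seed)
}

#' Evaluate a decision-criterion model against reference data
#'
#' For every integration length in `L_grid`, simulates the suite's
#' experiments with `n_participants` virtual listeners, aggregates responses
#' to the reference's condition cells, and computes the pooled RMS error
#' across all cells of all experiments. Returns the RMS-vs-L profile, the
#' best integration length and the Pearson correlation between model and
#' reference cell means at that length. The same per-participant seeds are
#' used at every L (common random numbers), so the profile reflects the
#' integration length alone.
#'
#' @param reference a `condition_summary` tibble (simulated or external).
#' @param suite an experiment suite (see [simulate_reference()]).
#' @param model_type `"st"`, `"lt"` or `"st_lt"` (sets `alpha` to 1, 0, 0.5
#'   and the long-term mode to the unprocessed-domain median for the pure LT
#'   model, the session median inside the mixture).
#' @param L_grid integration lengths in seconds.
#' @param alpha optional explicit short-term weight overriding `model_type`.
#' @param n_participants cohort size per simulation.
#' @param lapse_rate lapse rate of the simulated listeners.
#' @param seed master seed.
#' @param weighting RMS pooling, `"none"` or `"experiment"`.
#' @return An object of class `brightness_eval`.
#' @export
evaluate_model <- function(reference, suite,
                           model_type = c("st", "lt", "st_lt"),
                           L_grid = c(4, 8, 16, 32, 64, 128, 256),
                           alpha = NULL, n_participants = 50,
                           lapse_rate = 0.05, seed = 1,
                           weighting = c("none", "experiment")) {
  model_type <- match.arg(model_type)
  weighting <- match.arg(weighting)
  if (is.null(alpha)) {
    alpha <- switch(model_type, st = 1, lt = 0, st_lt = 0.5)
  }
  lt_mode <- if (model_type == "lt") "unprocessed_domain_median" else "session_median"
  seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1, 2 * n_participants), ncol = 2)
  })
  key_cols <- c("experiment", "context", "coloration", "prev_class")
  ref <- reference[!is.na(reference$p_bright), ]
  rms <- numeric(length(L_grid))
  cell_store <- vector("list", length(L_grid))
  for (li in seq_along(L_grid)) {
    params <- decision_params(alpha = alpha, integration_length_s = L_grid[li],
                              lapse_rate = lapse_rate, lt_mode = lt_mode,
                              lt_reference_hz = 1)  # per-experiment value set inside
    cells <- simulate_suite_cells(suite, params, n_participants, seed,
                                  participant_seeds = seeds)
    j <- dplyr::inner_join(ref, cells, by = key_cols,
                           suffix = c("_ref", "_mod"))
    missing <- dplyr::anti_join(ref, cells, by = key_cols)
    if (nrow(missing) > 0) {
      abort(paste0("model cells missing for reference cells: ",
                   paste(utils::head(do.call(paste, missing[key_cols]), 5),
                         collapse = "; ")))
    }
    j <- j[!is.na(j$p_bright_mod), ]
    rms[li] <- pooled_rms(j$p_bright_mod, j$p_bright_ref, j$experiment,
                          weighting)
    cell_store[[li]] <- j
  }
  best <- which.min(rms)
  jb <- cell_store[[best]]
  structure(list(
    rms_by_L = tibble(L = L_grid, rms = rms),
    best_L = L_grid[best],
    pearson_r = stats::cor(jb$p_bright_mod, jb$p_bright_ref),
    model_type = model_type, alpha = alpha,
    n_participants = n_participants,
    cells_at_best = jb
  ), class = "brightness_eval")
}

#' @export
print.brightness_eval <- function(x, ...) {
  cat(sprintf("<brightness_eval: %s model (alpha = %g), %d virtual participants>\n",
              x$model_type, x$alpha, x$n_participants))
  cat(sprintf("  best L = %g s, RMS = %.4f, Pearson r = %.3f\n", x$best_L,
              min(x$rms_by_L$rms), x$pearson_r))
  invisible(x)
}
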