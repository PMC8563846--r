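#' Parameters of the decision-criterion model
#'
#' A virtual listener judges a stimulus *bright* when its spectral centroid
#' exceeds a criterion that mixes a short-term term (the median SC over the
#' last `integration_length_s` seconds of stimulation, silences excluded)
#' with weight `alpha`, and a long-term term with weight `1 - alpha`.
#' `alpha = 1` is the pure short-term (ST) model, `alpha = 0` the fixed
#' long-term (LT) model, `alpha = 0.5` the ST+LT mixture. With probability
#' `lapse_rate` the emitted response contradicts the criterion.
#'
#' @param alpha short-term weight in `[0, 1]`.
#' @param integration_length_s integration length L in seconds (> 0).
#' @param lapse_rate probability of a response lapse, in `[0, 0.5)`.
#' @param lt_mode long-term term: `"session_median"` (median over all SCs of
#'   the session's filtered stimuli) or `"unprocessed_domain_median"` (median
#'   SC of the unfiltered corpus of the stimulus domain, supplied via
#'   `lt_reference_hz`).
#' @param first_trial_policy `"skip"` (no response on trial 1, which has no
#'   history) or `"chance"` (coin flip). Ignored when `alpha = 0`, where the
#'   criterion needs no history.
#' @param lt_reference_hz the unprocessed-domain median SC in Hz (required
#'   when it enters the criterion).
#' @return An object of class `decision_params`.
#' @export
decision_params <- function(alpha = 1, integration_length_s = 16,
                            lapse_rate = 0.05,
                            lt_mode = c("session_median",
                                        "unprocessed_domain_median"),
                            first_trial_policy = c("skip", "chance"),
                            lt_reference_hz = NULL) {
  lt_mode <- match.arg(lt_mode)
  first_trial_policy <- match.arg(first_trial_policy)
  stopifnot(alpha >= 0, alpha <= 1, integration_length_s > 0,
            lapse_rate >= 0, lapse_rate < 0.5)
  if (alpha < 1 && lt_mode == "unprocessed_domain_median" &&
      is.null(lt_reference_hz)) {
    abort("lt_mode = 'unprocessed_domain_median' needs lt_reference_hz.")
  }
  structure(list(alpha = alpha, integration_length_s = integration_length_s,
                 lapse_rate = lapse_rate, lt_mode = lt_mode,
                 first_trial_policy = first_trial_policy,
                 lt_reference_hz = lt_reference_hz),
            class = "decision_params")
}

#' @export
print.decision_params <- function(x, ...) {
  cat(sprintf(
    "<decision_params: alpha = %g, L = %g s, lapse = %g, lt = %s, first trial = %s>\n",
    x$alpha, x$integration_length_s, x$lapse_rate, x$lt_mode,
    x$first_trial_policy))
  invisible(x)
}

#' Short-term memory window of a trial
#'
#' The SC values entering the short-term criterion at trial `n`: trials
#' `n-1, n-2, ...` walking backwards while the running sum of their stimulus
#' durations stays below `L` seconds, always including at least trial `n-1`
#' and never trial `n` itself. Inter-trial silences do not count.
#'
#' @param history a tibble (or data frame) with columns `sc_hz` and
#'   `duration_s`, ordered by trial index.
#' @param n 1-based index of the current trial (>= 2).
#' @param L integration length in seconds.
#' @return Numeric vector of SC values (most recent last).
#' @export
st_window <- function(history, n, L) {
  if (n < 2) abort("trial 1 has no history: the short-term window is empty.")
  j <- n - 1
  total <- 0
  start <- j
  while (start >= 1) {
    total <- total + history$duration_s[start]
    if (total >= L || start == 1) break
    start <- start - 1
  }
  history$sc_hz[start:(n - 1)]
}

#' Decision criterion at a trial
#'
#' `alpha * med(ST window) + (1 - alpha) * med(LT term)`, where the LT term
#' is the median over all session SCs (`lt_mode = "session_median"`) or the
#' unprocessed-domain median (`lt_mode = "unprocessed_domain_median"`).
#'
#' @inheritParams st_window
#' @param params a [decision_params()] object.
#' @return Criterion in Hz.
#' @export
decision_criterion <- function(history, n, params) {
  stopifnot(inherits(params, "decision_params"))
  lt <- if (params$alpha < 1) lt_term(history, params) else 0
  st <- if (params$alpha > 0) stats::median(st_window(history, n, params$integration_length_s)) else 0
  params$alpha * st + (1 - params$alpha) * lt
}

lt_term <- function(history, params) {
  if (params$lt_mode == "session_median") {
    stats::median(history$sc_hz)
  } else {
    params$lt_reference_hz
  }
}

#' Emit bright/dull responses given criteria
#'
#' The base response is *bright* iff `sc_hz > criterion_hz` (strict; ties are
#' *dull*). With probability `lapse_rate` the response is flipped and flagged
#' as a lapse.
#'
#' @param sc_hz stimulus SC value(s).
#' @param criterion_hz criterion value(s), recycled against `sc_hz`.
#' @param lapse_rate lapse probability.
#' @param seed optional RNG seed for the lapse stream.
#' @return A tibble with columns `response` ("bright"/"dull") and `lapsed`.
#' @export
respond <- function(sc_hz, criterion_hz, lapse_rate = 0.05, seed = NULL) {
  draw <- function() stats::runif(length(sc_hz)) < lapse_rate
  lapsed <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  bright <- xor(sc_hz > criterion_hz, lapsed)
  tibble(response = ifelse(bright, "bright", "dull"), lapsed = lapsed)
}

# Criterion series over a whole session: one value per trial (NA on trial 1
# when the short-term term is engaged).
criterion_series <- function(sc_hz, duration_s, params) {
  n <- length(sc_hz)
  history <- list(sc_hz = sc_hz, duration_s = duration_s)
  lt <- if (params$alpha < 1) lt_term(history, params) else 0
  crit <- rep(NA_real_, n)
  if (params$alpha == 0) return(rep(lt, n))
  cum <- cumsum(duration_s)
  for (i in 2:n) {
    # smallest start with cum[i-1] - cum[start-1] >= L, but at least trial i-1
    tgt <- cum[i - 1] - params$integration_length_s
    start <- min(findInterval(tgt, cum, left.open = FALSE) + 1, i - 1)
    st <- stats::median(sc_hz[start:(i - 1)])
    crit[i] <- params$alpha * st + (1 - params$alpha) * lt
  }
  crit
}

#' Simulate one virtual participant over a session design
#'
#' Applies the decision criterion and response rule sequentially over the
#' trials of a session. Adaptor trials are answered like any other trial and
#' enter the short-term history through their stimulus durations.
#'
#' @param design a `session_design` tibble (one session).
#' @param sc_table a tibble `excerpt_id`, `coloration`, `sc_hz` covering every
#'   trial (see [sc_slope_table()] / [sc_morph_table()]).
#' @param params a [decision_params()] object.
#' @param seed RNG seed for the lapse stream.
#' @return The design tibble augmented with `sc_hz`, `criterion_hz`,
#'   `response` ("bright"/"dull"/"none") and `lapsed`.
#' @export
run_virtual_participant <- function(design, sc_table, params, seed = 1) {
  stopifnot(inherits(params, "decision_params"))
  key <- paste(design$excerpt_id, design$coloration)
  m <- match(key, paste(sc_table$excerpt_id, sc_table$coloration))
  if (anyNA(m)) {
    abort(sprintf("no SC value for trial %d (excerpt %s, coloration %s).",
                  design$index_n[which(is.na(m))[1]],
                  design$excerpt_id[which(is.na(m))[1]],
                  format(design$coloration[which(is.na(m))[1]])))
  }
  sc <- sc_table$sc_hz[m]
  crit <- criterion_series(sc, design$duration_s, params)
  out <- design
  out$sc_hz <- sc
  out$criterion_hz <- crit
  withr::with_seed(seed, {
    resp <- respond(sc, crit, params$lapse_rate)
    if (is.na(crit[1])) {
      if (params$first_trial_policy == "skip") {
        resp$response[1] <- "none"
        resp$lapsed[1] <- NA
      } else {
        resp$response[1] <- sample(c("bright", "dull"), 1)
        resp$lapsed[1] <- FALSE
      }
    }
  })
  out$response <- resp$response
  out$lapsed <- resp$lapsed
  out
}

#' Simulate a cohort of virtual participants
#'
#' Each participant receives an independent design randomization (via
#' `design_fn`) and an independent lapse stream; sessions within a design are
#' simulated separately (the criterion never crosses session boundaries).
#'
#' @param design_fn function of a single seed returning a `session_design`
#'   tibble (possibly several sessions bound together, distinguished by
#'   `session_id`).
#' @param sc_table SC lookup table covering all designs.
#' @param params a [decision_params()] object.
#' @param n_participants number of virtual participants.
#' @param seed master seed; per-participant seeds are derived from it.
#' @param participant_seeds optional matrix (n x 2) of explicit per-participant
#'   design and response seeds (for common-random-number comparisons).
#' @return A response tibble over all participants with a `participant` column.
#' @export
simulate_participants <- function(design_fn, sc_table, params,
                                  n_participants = 50, seed = 1,
                                  participant_seeds = NULL) {
  if (is.null(participant_seeds)) {
    participant_seeds <- withr::with_seed(seed, {
      matrix(sample.int(.Machine$integer.max - 1, 2 * n_participants),
             ncol = 2)
    })
  }
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    des <- design_fn(participant_seeds[i, 1])
    sessions <- split(des, des$session_id)
    runs <- lapply(seq_along(sessions), function(k) {
      run_virtual_participant(sessions[[k]], sc_table, params,
                              seed = participant_seeds[i, 2] + k)
    })
    res <- dplyr::bind_rows(runs)
    res$participant <- sprintf("vp%03d", i)
    out[[i]] <- res
  }
  dplyr::relocate(dplyr::bind_rows(out), "participant")
}
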