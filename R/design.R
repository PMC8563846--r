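#' Filter-slope sets of the slope experiments
#'
#' The first experiment presents seven slopes between -2 and +2 dB/oct; the
#' global-context experiment shifts that whole set by -1 or +1 dB/oct.
#' @export
exp1_slopes <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2)

#' @rdname exp1_slopes
#' @param context `"shift_minus_1"` or `"shift_plus_1"`.
#' @export
exp3_slopes <- function(context = c("shift_minus_1", "shift_plus_1")) {
  context <- match.arg(context)
  exp1_slopes() + if (context == "shift_minus_1") -1 else 1
}

#' Morph-level grids of the transfer-function experiment
#'
#' Six levels per session, 50 trials each; the two session grids cover
#' down-shifted versus up-shifted sub-ranges of `[-0.5, 1.5]` and share the
#' interior levels 0.25--0.75.
#' @param context `"device_context"` or `"openear_context"`.
#' @export
exp4_morph_levels <- function(context = c("device_context", "openear_context")) {
  context <- match.arg(context)
  if (context == "device_context") {
    c(-0.5, -0.25, 0, 0.25, 0.5, 0.75)
  } else {
    c(0.25, 0.5, 0.75, 1.0, 1.25, 1.5)
  }
}

# Draw n excerpt rows (without replacement) of a given duration.
draw_excerpts <- function(corpus, n, duration_s = NULL, exclude = character()) {
  pool <- corpus
  if (!is.null(duration_s)) {
    pool <- pool[abs(pool$duration_s - duration_s) < 0.5 / 44100 |
                   (duration_s == 2 & pool$domain == "speech"), ]
  }
  pool <- pool[!pool$excerpt_id %in% exclude, ]
  if (nrow(pool) < n) {
    abort(sprintf("corpus too small: %d eligible excerpts, %d required.",
                  nrow(pool), n))
  }
  pool[sample.int(nrow(pool), n), c("excerpt_id", "speaker_id", "domain",
                                    "duration_s")]
}

# Reorder rows so that no two consecutive rows share speaker_id, by repeated
# repair swaps. Deterministic under the caller's RNG state.
enforce_speaker_succession <- function(rows, max_iter = 5000) {
  spk <- rows$speaker_id
  if (all(is.na(spk))) return(rows)
  ord <- seq_len(nrow(rows))
  for (iter in seq_len(max_iter)) {
    bad <- which(spk[ord][-1] == spk[ord][-length(ord)]) + 1
    if (length(bad) == 0) return(rows[ord, ])
    i <- bad[1]
    cand <- which(vapply(seq_along(ord), function(j) {
      if (j == i) return(FALSE)
      sj <- spk[ord[j]]; si <- spk[ord[i]]
      okj <- (j == 1 || spk[ord[j - 1]] != si) &&
        (j == length(ord) || j + 1 == i || spk[ord[j + 1]] != si)
      oki <- (i == 1 || j == i - 1 || spk[ord[i - 1]] != sj) &&
        (i == length(ord) || spk[ord[i + 1]] != sj)
      okj && oki
    }, logical(1)))
    if (length(cand) == 0) break
    j <- cand[sample.int(length(cand), 1)]
    ord[c(i, j)] <- ord[c(j, i)]
  }
  abort("could not arrange excerpts without consecutive same-speaker trials.")
}

new_session_design <- function(trials, experiment, context, domain, level_set,
                               session_id) {
  trials$session_id <- session_id
  trials$experiment <- experiment
  trials$context <- context
  out <- dplyr::relocate(trials, "session_id", "experiment", "context",
                         "domain", "index_n")
  attr(out, "level_set") <- level_set
  class(out) <- c("session_design", class(out))
  out
}

design_slope_session <- function(corpus, slopes, seed, experiment, context,
                                 session_id) {
  n_trials <- 50 * length(slopes)
  withr::with_seed(seed, {
    ex <- draw_excerpts(corpus, n_trials, duration_s = 2)
    ex <- enforce_speaker_succession(ex)
    coloration <- sample(rep(slopes, each = 50))
  })
  trials <- tibble(
    domain = ex$domain,
    index_n = seq_len(n_trials),
    role = "target",
    coloration = coloration,
    duration_s = ex$duration_s,
    excerpt_id = ex$excerpt_id,
    speaker_id = ex$speaker_id
  )
  new_session_design(trials, experiment, context, unique(ex$domain)[1],
                     slopes, session_id)
}

#' Trial sequence for the baseline slope experiment
#'
#' 350 trials, 50 at each slope in `exp1_slopes()`, order uniformly random,
#' all 2-s targets, no excerpt repeated, and (for speech corpora) no two
#' consecutive trials by the same speaker.
#'
#' @param corpus a corpus tibble (needs >= 350 eligible 2-s excerpts; the
#'   waveforms themselves are not required, a manifest suffices).
#' @param seed RNG seed.
#' @param session_id label for the session.
#' @return A `session_design` tibble with columns `session_id`, `experiment`,
#'   `context`, `domain`, `index_n`, `role`, `coloration`, `duration_s`,
#'   `excerpt_id`, `speaker_id`.
#' @export
design_exp1 <- function(corpus, seed = 1, session_id = "exp1_s1") {
  design_slope_session(corpus, exp1_slopes(), seed, "exp1", "none", session_id)
}

#' Trial sequence for the global-context slope experiment
#'
#' Identical to [design_exp1()] but with the slope set shifted by -1 or +1
#' dB/oct according to `context`; the two contexts share slopes -1, 0 and +1.
#'
#' @inheritParams design_exp1
#' @param context `"shift_minus_1"` or `"shift_plus_1"`.
#' @export
design_exp3 <- function(corpus, context = c("shift_minus_1", "shift_plus_1"),
                        seed = 1, session_id = NULL) {
  context <- match.arg(context)
  if (is.null(session_id)) session_id <- paste0("exp3_", context)
  design_slope_session(corpus, exp3_slopes(context), seed, "exp3", context,
                       session_id)
}

# Balanced adaptor allocation: 75 adaptors per context slope, durations
# 38/37/38/37 over 1/2/4/8 s (row sums 75, column sums as stated).
exp2_adaptor_allocation <- function() {
  m <- matrix(c(19, 19, 19, 18,
                19, 18, 19, 19), nrow = 2, byrow = TRUE,
              dimnames = list(c("-1", "1"), c("1", "2", "4", "8")))
  m
}

#' Trial sequence for the adaptor-duration experiment
#'
#' 300 trials alternating hidden adaptors and targets: 150 adaptor trials
#' (slope -1 or +1 dB/oct, durations 1/2/4/8 s) interleaved with 150 2-s
#' target trials (slopes -1, 0, +1 dB/oct, 50 each). Responses are collected
#' on every trial; only targets are flagged for analysis. With
#' `balancing = "balanced"` (default) adaptor slopes and durations are
#' counterbalanced exactly; `"random"` draws them independently per trial.
#'
#' @inheritParams design_exp1
#' @param balancing `"balanced"` or `"random"`.
#' @export
design_exp2 <- function(corpus, seed = 1, balancing = c("balanced", "random"),
                        session_id = "exp2_s1") {
  balancing <- match.arg(balancing)
  durations <- c(1, 2, 4, 8)
  have <- vapply(durations, function(d) {
    any(abs(corpus$duration_s - d) < 0.5 / 44100)
  }, logical(1))
  if (!all(have)) {
    abort(sprintf("corpus is missing adaptor duration class(es): %s s.",
                  paste(durations[!have], collapse = ", ")))
  }
  withr::with_seed(seed, {
    target_slope <- sample(rep(c(-1, 0, 1), each = 50))
    if (balancing == "balanced") {
      alloc <- exp2_adaptor_allocation()
      ad <- tidyr::expand_grid(slope = c(-1, 1), dur = durations)
      counts <- alloc[cbind(match(ad$slope, c(-1, 1)), match(ad$dur, durations))]
      ad <- ad[rep(seq_len(nrow(ad)), counts), ]
      ad <- ad[sample.int(nrow(ad)), ]
    } else {
      ad <- tibble(slope = sample(c(-1, 1), 150, replace = TRUE),
                   dur = sample(durations, 150, replace = TRUE))
    }
    targets <- draw_excerpts(corpus, 150, duration_s = 2)
    used <- targets$excerpt_id
    ad_rows <- vector("list", length(durations))
    for (k in seq_along(durations)) {
      nk <- sum(abs(ad$dur - durations[k]) < 1e-9)
      ad_rows[[k]] <- draw_excerpts(corpus, nk, duration_s = durations[k],
                                    exclude = used)
      used <- c(used, ad_rows[[k]]$excerpt_id)
    }
  })
  ad_ex <- dplyr::bind_rows(ad_rows)
  # attach the drawn excerpts to adaptor slots of matching duration
  ad$excerpt_id <- NA_character_
  ad$speaker_id <- NA_character_
  for (k in seq_along(durations)) {
    slot <- which(abs(ad$dur - durations[k]) < 1e-9)
    rows <- which(abs(ad_ex$duration_s - durations[k]) < 0.5 / 44100)
    ad$excerpt_id[slot] <- ad_ex$excerpt_id[rows[seq_along(slot)]]
    ad$speaker_id[slot] <- ad_ex$speaker_id[rows[seq_along(slot)]]
  }
  trials <- tibble(
    domain = unique(corpus$domain)[1],
    index_n = seq_len(300),
    role = rep(c("adaptor", "target"), times = 150),
    coloration = as.numeric(rbind(ad$slope, target_slope)),
    duration_s = as.numeric(rbind(ad$dur, rep(2, 150))),
    excerpt_id = as.character(rbind(ad$excerpt_id, targets$excerpt_id)),
    speaker_id = as.character(rbind(ad$speaker_id, targets$speaker_id))
  )
  new_session_design(trials, "exp2", "none", unique(corpus$domain)[1],
                     c(-1, 0, 1), session_id)
}

#' Trial sequence for the transfer-function morph experiment
#'
#' 300 2-s target trials, 50 at each of the six morph levels of the requested
#' context grid (see [exp4_morph_levels()]); otherwise as [design_exp1()].
#'
#' @inheritParams design_exp1
#' @param tf_pair optional `tf_pair` (validated if supplied; the design holds
#'   morph levels, not audio).
#' @param context `"device_context"` or `"openear_context"`.
#' @export
design_exp4 <- function(corpus, tf_pair = NULL,
                        context = c("device_context", "openear_context"),
                        seed = 1, session_id = NULL) {
  context <- match.arg(context)
  if (!is.null(tf_pair) && !inherits(tf_pair, "tf_pair")) {
    abort("tf_pair must be a tf_pair object (see generate_transfer_function_pair()).")
  }
  if (is.null(session_id)) session_id <- paste0("exp4_", context)
  levels <- exp4_morph_levels(context)
  withr::with_seed(seed, {
    ex <- draw_excerpts(corpus, 300, duration_s = 2)
    ex <- enforce_speaker_succession(ex)
    coloration <- sample(rep(levels, each = 50))
  })
  trials <- tibble(
    domain = ex$domain,
    index_n = seq_len(300),
    role = "target",
    coloration = coloration,
    duration_s = ex$duration_s,
    excerpt_id = ex$excerpt_id,
    speaker_id = ex$speaker_id
  )
  new_session_design(trials, "exp4", context, unique(ex$domain)[1], levels,
                     session_id)
}
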