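#' Assemble an experiment suite for simulation and model evaluation
#'
#' Bundles, per requested experiment, a per-participant design randomizer, a
#' precomputed spectral-centroid lookup table covering every (excerpt,
#' coloration) pair the designs can draw, and the unprocessed-domain median
#' SC used by the long-term criterion. The result feeds
#' [simulate_reference()] and [evaluate_model()].
#'
#' @param music_corpus a 2-s music corpus tibble with waveforms (>= 350
#'   excerpts for the 350-trial designs).
#' @param experiments subset of `c("exp1", "exp2", "exp3", "exp4")`.
#' @param speech_corpus optional speech corpus; when supplied, the baseline
#'   experiment also includes a speech session.
#' @param adaptor_corpus corpus providing 1/4/8-s excerpts for the hidden
#'   adaptor experiment (2-s adaptors come from `music_corpus`).
#' @param tf_pair a `tf_pair` for the morph experiment.
#' @param rate sampling rate in Hz.
#' @return A named list of experiment entries (`experiment`, `design_fn`,
#'   `sc_table`, `lt_reference_hz`), class `experiment_suite`.
#' @export
experiment_suite <- function(music_corpus,
                             experiments = c("exp1", "exp3"),
                             speech_corpus = NULL, adaptor_corpus = NULL,
                             tf_pair = NULL, rate = 44100) {
  experiments <- match.arg(experiments, c("exp1", "exp2", "exp3", "exp4"),
                           several.ok = TRUE)
  slopes <- c()
  if ("exp1" %in% experiments) slopes <- c(slopes, exp1_slopes())
  if ("exp2" %in% experiments) slopes <- c(slopes, -1, 0, 1)
  if ("exp3" %in% experiments) {
    slopes <- c(slopes, exp3_slopes("shift_minus_1"), exp3_slopes("shift_plus_1"))
  }
  slopes <- sort(unique(slopes))
  music_sc <- NULL
  if (length(slopes) > 0) {
    music_sc <- sc_slope_table(music_corpus, slopes, rate = rate)
  }
  suite <- list()
  if ("exp1" %in% experiments) {
    sc <- music_sc
    lt <- domain_median_sc(music_sc)
    fn <- function(seed) design_exp1(music_corpus, seed)
    if (!is.null(speech_corpus)) {
      speech_sc <- sc_slope_table(speech_corpus, exp1_slopes(), rate = rate)
      sc <- dplyr::bind_rows(music_sc, speech_sc)
      lt_s <- domain_median_sc(speech_sc)
      fn <- function(seed) {
        dplyr::bind_rows(
          design_exp1(music_corpus, seed, session_id = "exp1_music"),
          design_exp1(speech_corpus, seed + 1, session_id = "exp1_speech"))
      }
    }
    suite$exp1 <- list(experiment = "exp1", design_fn = fn, sc_table = sc,
                       lt_reference_hz = lt)
  }
  if ("exp2" %in% experiments) {
    if (is.null(adaptor_corpus)) {
      abort("exp2 needs an adaptor_corpus with 1, 4 and 8 s excerpts.")
    }
    corpus2 <- dplyr::bind_rows(music_corpus, adaptor_corpus)
    ad_sc <- sc_slope_table(adaptor_corpus, c(-1, 0, 1), rate = rate)
    sc2 <- dplyr::bind_rows(music_sc, ad_sc)
    suite$exp2 <- list(
      experiment = "exp2",
      design_fn = function(seed) design_exp2(corpus2, seed),
      sc_table = sc2,
      lt_reference_hz = domain_median_sc(music_sc))
  }
  if ("exp3" %in% experiments) {
    suite$exp3 <- list(
      experiment = "exp3",
      design_fn = function(seed) {
        dplyr::bind_rows(design_exp3(music_corpus, "shift_minus_1", seed),
                         design_exp3(music_corpus, "shift_plus_1", seed + 1))
      },
      sc_table = music_sc,
      lt_reference_hz = domain_median_sc(music_sc))
  }
  if ("exp4" %in% experiments) {
    if (is.null(tf_pair)) abort("exp4 needs a tf_pair.")
    morphs <- sort(unique(c(exp4_morph_levels("device_context"),
                            exp4_morph_levels("openear_context"))))
    morph_sc <- sc_morph_table(music_corpus, tf_pair, morphs, rate = rate)
    suite$exp4 <- list(
      experiment = "exp4",
      design_fn = function(seed) {
        dplyr::bind_rows(
          design_exp4(music_corpus, tf_pair, "device_context", seed),
          design_exp4(music_corpus, tf_pair, "openear_context", seed + 1))
      },
      sc_table = morph_sc,
      lt_reference_hz = domain_median_sc(morph_sc))
  }
  structure(suite, class = c("experiment_suite", "list"))
}
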