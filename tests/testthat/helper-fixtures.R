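# Shared fixtures, built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, expr, envir = .fixtures)
  .fixtures[[name]]
}

# full-size music corpus feeding the 350-trial designs and the model suite
music_350 <- function() fixture("m350", generate_music_corpus(350, 2, seed = 101))

music_20 <- function() fixture("m20", generate_music_corpus(20, 2, seed = 11))

speech_small <- function() fixture("sp", generate_speech_corpus(3, 10, seed = 2))

tf_pair_6 <- function() {
  fixture("tf6", generate_transfer_function_pair(seed = 1, contrast_db = 6))
}

suite_13 <- function() {
  fixture("s13", experiment_suite(music_350(), c("exp1", "exp3")))
}

# metadata-only corpus manifest: enough for trial-design generation, which
# never touches waveforms
fake_corpus <- function(n, domain = "music", duration_s = 2, n_speakers = 0) {
  tibble::tibble(
    excerpt_id = sprintf("fx%s_%04d", substr(domain, 1, 3), seq_len(n)),
    domain = domain,
    speaker_id = if (n_speakers > 0) {
      sprintf("spk%02d", rep_len(seq_len(n_speakers), n))
    } else NA_character_,
    duration_s = duration_s,
    rate = 44100
  )
}

# manifest with all four adaptor duration classes for the exp2 design
fake_corpus_exp2 <- function() {
  dplyr::bind_rows(
    fake_corpus(200, duration_s = 2),
    fake_corpus(45, duration_s = 1),
    fake_corpus(45, duration_s = 4),
    fake_corpus(45, duration_s = 8)
  ) |>
    dplyr::mutate(excerpt_id = sprintf("fx2_%s_%04d", duration_s,
                                       seq_along(excerpt_id)))
}

# small hand-rolled session design + SC table for decision-model unit tests
toy_design <- function(n = 20, sc = NULL, durations = rep(2, n)) {
  tibble::tibble(
    session_id = "toy", experiment = "exp1", context = "none",
    domain = "music", index_n = seq_len(n), role = "target",
    coloration = rep_len(c(-1, 0, 1), n), duration_s = durations,
    excerpt_id = sprintf("toy%03d", seq_len(n)),
    speaker_id = NA_character_
  )
}

toy_sc_table <- function(design, sc) {
  tibble::tibble(excerpt_id = design$excerpt_id,
                 coloration = design$coloration, sc_hz = sc)
}
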