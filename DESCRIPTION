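Package: brightadapt
Title: Simulation and Modelling of Adaptive Auditory Brightness Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying contrastive adaptation of auditory brightness
    judgments with synthetic music- and speech-like stimuli. Generates
    spectrally controlled audio corpora and synthetic acoustic transfer
    functions, applies octave-filterbank spectral-slope colorations and
    transfer-function morphs, computes the ERB-grouped spectral centroid
    brightness feature, builds randomized trial sequences for four
    psychophysical experiment designs, simulates virtual listeners with a
    short-term/long-term decision-criterion model including a lapse rate, and
    evaluates model variants against reference response data via pooled RMS
    error over integration lengths, bootstrap confidence intervals, adaptation
    contrasts, response trajectories, and a fixed-effects logistic summarizer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
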