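#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the RMS-vs-integration-length profile of a model evaluation
#'
#' @param x a `brightness_eval` object.
#' @param ... ignored.
#' @return A tibble with columns `L` and `rms`.
#' @exportS3Method generics::tidy
tidy.brightness_eval <- function(x, ...) {
  x$rms_by_L
}

#' One-row summary of a model evaluation
#'
#' @param x a `brightness_eval` object.
#' @param ... ignored.
#' @exportS3Method generics::glance
glance.brightness_eval <- function(x, ...) {
  tibble(model_type = x$model_type, alpha = x$alpha, best_L = x$best_L,
         rms_min = min(x$rms_by_L$rms), pearson_r = x$pearson_r,
         n_participants = x$n_participants)
}

#' Coefficient table of the fixed-effects logistic summarizer
#'
#' @param x a `context_logit` object.
#' @param ... ignored.
#' @exportS3Method generics::tidy
tidy.context_logit <- function(x, ...) {
  x$table
}

#' One-row summary of the logistic summarizer fit
#'
#' @param x a `context_logit` object.
#' @param ... ignored.
#' @exportS3Method generics::glance
glance.context_logit <- function(x, ...) {
  tibble(experiment = x$experiment, n = x$n,
         deviance = stats::deviance(x$fit),
         converged = x$fit$converged, separated = x$separated)
}
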