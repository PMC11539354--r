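# broom-style tidiers for fitted objects.

#' Tidy a behavior-model fit set
#'
#' One row per coefficient per model (lick-only, P(S)-only, combined).
#'
#' @param x A [accuracy_behavior_models()] result.
#' @param ... Unused.
#' @return A tibble `model`, `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.behavior_model_fits <- function(x, ...) {
  purrr::map_dfr(c("lick_only", "ps_only", "combined"), function(nm) {
    s <- summary(x[[nm]])$coefficients
    tibble(model = nm, term = rownames(s), estimate = s[, 1],
           std_error = s[, 2], statistic = s[, 3], p_value = s[, 4])
  })
}

#' @rdname tidy.behavior_model_fits
#' @export
glance.behavior_model_fits <- function(x, ...) {
  purrr::map_dfr(c("lick_only", "ps_only", "combined"), function(nm) {
    s <- summary(x[[nm]])
    tibble(model = nm, r_squared = s$r.squared,
           adj_r_squared = s$adj.r.squared,
           sigma = s$sigma, df_residual = x[[nm]]$df.residual)
  })
}

#' Tidy a distributed-lag model
#'
#' @param x A [distributed_lag_model()] fit.
#' @param ... Unused.
#' @return The coefficient tibble (`lag`, `channel`, `estimate`).
#' @export
tidy.distributed_lag_model <- function(x, ...) x$coefficients

#' @rdname tidy.distributed_lag_model
#' @export
glance.distributed_lag_model <- function(x, ...) {
  tibble(r_squared = x$r2, r_squared_cv = x$r2_cv,
         n_terms = nrow(x$coefficients), ridge = x$ridge)
}

#' Tidy a face-feature lick classifier
#'
#' @param x A [face_lick_classifier()] fit.
#' @param ... Unused.
#' @return A tibble of logistic coefficients.
#' @export
tidy.face_lick_classifier <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @rdname tidy.face_lick_classifier
#' @export
glance.face_lick_classifier <- function(x, ...) {
  tibble(cv_accuracy = x$cv_accuracy, n_frames = length(x$probability))
}

#' Summarize a participation-ratio result
#'
#' @param x A [participation_ratio()] or [subsampled_pr()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.pr_result <- function(x, ...) {
  tibble(pr = x$pr,
         k = x$k %||% x$n_neurons,
         n_resamples = x$n_resamples %||% 1L,
         sd_resamples = if (!is.null(x$per_resample)) sd(x$per_resample) else NA_real_)
}

#' Summarize a cross-day transfer result
#'
#' @param x A [cross_day_transfer()] result.
#' @param ... Unused.
#' @return A one-row tibble `fraction`, `n_pairs`, `mean_magnitude_change`.
#' @export
glance.transfer_result <- function(x, ...) {
  tibble(fraction = x$fraction, n_pairs = x$n_pairs,
         mean_magnitude_change = mean(x$per_neuron$magnitude_change))
}
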