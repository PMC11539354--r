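# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a root seed and a stage name
#'
#' Each pipeline stage draws its randomness from a named substream so that
#' toggling one stage never perturbs another's random numbers. The derived
#' seed is a deterministic function of `(seed, label)` and always fits in a
#' 32-bit integer.
#'
#' @param seed Integer root seed.
#' @param label Character scalar naming the substream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) %% 1000003L) * 2017L + (h %% 999983L) * 31L + 1L) %% 2147483646L + 1L
}

# Stratified fold assignment: every class is spread as evenly as possible
# across folds. Returns an integer vector of fold ids aligned with `labels`.
stratified_folds <- function(labels, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      abort(sprintf(
        "class '%s' has %d trials, fewer than %d folds", cl, length(idx), folds
      ))
    }
    fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# Midrank (tie-corrected) two-sample rank statistic A = P(X1 > X0) + P(=)/2.
rank_auc_stat <- function(values, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  r <- rank(values) # midranks
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Half-open window [t0, t1): frames selected by their start time.
frames_in_window <- function(time_axis, window) {
  which(time_axis >= window[1] - 1e-9 & time_axis < window[2] - 1e-9)
}

# R^2 of an lm fit against the observed response.
r_squared <- function(fit) {
  y <- fit$model[[1]]
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}
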