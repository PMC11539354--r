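# Lick quantification, face-feature lick inference, distributed-lag
# modeling, and the contingency-vs-vigor decoupling regressions.

#' Per-odor lick rates, sucrose-cue fraction, and learning trends
#'
#' Quantifies anticipatory licking inside an analysis window relative to
#' odor onset: licks/s per odor, the fraction of odor-period licks that
#' occur during sucrose-contingent odors, and a trailing moving-average
#' trend of per-trial lick counts for each odor.
#'
#' @param behavior A [simulate_behavior()] trace (or compatible list).
#' @param trials A [build_trial_table()] table.
#' @param window `[t0, t1)` in s relative to odor onset (the 2 s odor
#'   period by default; use `c(1.5, 2.5)` for the lick-spout paradigm's
#'   last-0.5 s-odor + first-0.5 s-delay bin).
#' @param ma_window Trials in the trailing moving-average trend.
#' @return A list of class `lick_metrics`: `per_trial` (tibble
#'   `trial_index`, `odor`, `licks`, `rate`, `trend`), `per_odor` (tibble
#'   `odor`, `rate`), `s_fraction` (fraction of in-window licks during
#'   sucrose-contingent odors; `NA` with a warning if no licks at all).
#' @export
lick_metrics <- function(behavior, trials, window = c(0, 2), ma_window = 10) {
  per_trial <- anticipatory_licks(behavior, trials, window)
  dur <- diff(window)
  per_trial$rate <- per_trial$licks / dur
  per_trial <- per_trial |>
    dplyr::group_by(.data$odor) |>
    dplyr::mutate(trend = trailing_ma(.data$licks, ma_window)) |>
    dplyr::ungroup()

  per_odor <- per_trial |>
    dplyr::group_by(.data$odor) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop")

  scheme <- attr(trials, "scheme")
  v <- odor_value(scheme)
  s_odors <- names(v)[v == max(v) & v > 0]
  total <- sum(per_trial$licks)
  s_fraction <- if (total == 0) {
    warn("no licks during any odor; sucrose-cue fraction undefined")
    NA_real_
  } else {
    sum(per_trial$licks[per_trial$odor %in% s_odors]) / total
  }
  structure(list(per_trial = per_trial, per_odor = per_odor,
                 s_fraction = s_fraction, window = window),
            class = "lick_metrics")
}

trailing_ma <- function(x, w) {
  vapply(seq_along(x), function(i) mean(x[max(1, i - w + 1):i]), numeric(1))
}

#' @export
print.lick_metrics <- function(x, ...) {
  cat(sprintf("<lick_metrics> window [%g, %g) s; sucrose-cue lick fraction %.3f\n",
              x$window[1], x$window[2], x$s_fraction))
  print(x$per_odor)
  invisible(x)
}

#' Infer licking from face features
#'
#' Trains a three-feature logistic classifier (tongue-tip confidence,
#' mouth-corner confidence, upper-lower lip distance) against
#' lick-sensor ground truth, reports stratified CV accuracy, and returns
#' per-frame lick probabilities -- usable on frames where the lick spout
#' (and hence the sensor) is absent.
#'
#' @param face_features `frames x 3` matrix.
#' @param lick_truth 0/1 (or logical) ground-truth lick state per frame.
#' @param folds Stratified CV folds.
#' @param seed Integer seed.
#' @return A list of class `face_lick_classifier`: `fit` (glm),
#'   `cv_accuracy`, `probability` (per input frame).
#' @export
face_lick_classifier <- function(face_features, lick_truth, folds = 5,
                                 seed = NULL) {
  y <- as.numeric(lick_truth) > 0
  if (length(unique(y)) < 2) abort("ground truth contains a single class")
  df <- as.data.frame(face_features)
  names(df) <- c("tongue_conf", "mouth_conf", "lip_dist")
  fold <- stratified_folds(y, folds, seed)
  correct <- logical(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- suppressWarnings(glm(y[tr] ~ ., data = df[tr, ], family = binomial()))
    correct[!tr] <- (predict(fit, df[!tr, ], type = "response") > 0.5) == y[!tr]
  }
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  structure(list(fit = fit, cv_accuracy = mean(correct),
                 probability = predict(fit, df, type = "response")),
            class = "face_lick_classifier")
}

#' @export
predict.face_lick_classifier <- function(object, face_features, ...) {
  df <- as.data.frame(face_features)
  names(df) <- c("tongue_conf", "mouth_conf", "lip_dist")
  predict(object$fit, df, type = "response")
}

#' Distributed-lag regression of a target on lagged regressors
#'
#' Least-squares fit of `y_t` on time-lagged copies of the regressor
#' channels, `x_{t+l}` for lags `l` in `lags[1]:lags[2]` (negative lags =
#' regressor precedes target). Out-of-sample performance comes from
#' contiguous-block cross-validation, which respects the serial structure.
#' An optional ridge penalty stabilizes collinear designs.
#'
#' @param x `frames x channels` regressor matrix (or vector).
#' @param y Target vector.
#' @param lags Integer `c(l_min, l_max)` in frames.
#' @param ridge Ridge penalty (0 = ordinary least squares).
#' @param cv_blocks Contiguous blocks for out-of-sample R^2.
#' @param seed Unused (fits are deterministic); kept for interface
#'   uniformity.
#' @return A list of class `distributed_lag_model`: `coefficients` tibble
#'   (`lag`, `channel`, `estimate`), `intercept`, `r2` (in-sample),
#'   `r2_cv` (block-CV out-of-sample), `fitted`, `lags`.
#' @export
distributed_lag_model <- function(x, y, lags = c(-10, 0), ridge = 0,
                                  cv_blocks = 5, seed = NULL) {
  x <- as.matrix(x)
  n <- length(y)
  lag_seq <- lags[1]:lags[2]
  if (length(lag_seq) >= n) abort("lag window must be shorter than the series")
  chans <- colnames(x) %||% paste0("x", seq_len(ncol(x)))

  # valid rows: all lagged copies in range
  lo <- max(1, 1 - min(lag_seq))
  hi <- min(n, n - max(lag_seq))
  rows <- lo:hi
  X <- do.call(cbind, lapply(lag_seq, function(l) x[rows + l, , drop = FALSE]))
  colnames(X) <- as.vector(outer(chans, lag_seq, function(c, l) paste0(c, "@", l)))
  yy <- y[rows]

  solve_ls <- function(X, yy) {
    Xc <- cbind(intercept = 1, X)
    XtX <- crossprod(Xc)
    if (ridge > 0) {
      XtX <- XtX + diag(c(0, rep(ridge, ncol(X))))
    } else {
      kappa_est <- tryCatch(kappa(XtX, exact = FALSE), error = function(e) Inf)
      if (!is.finite(kappa_est) || kappa_est > 1e12) {
        abort(sprintf("design is degenerate (condition number %.3g); use ridge > 0",
                      kappa_est))
      }
    }
    solve(XtX, crossprod(Xc, yy))
  }

  beta <- solve_ls(X, yy)
  fitted <- as.vector(cbind(1, X) %*% beta)
  r2 <- 1 - sum((yy - fitted)^2) / sum((yy - mean(yy))^2)

  block <- cut(seq_along(yy), cv_blocks, labels = FALSE)
  pred_cv <- numeric(length(yy))
  for (b in seq_len(cv_blocks)) {
    tr <- block != b
    bcv <- solve_ls(X[tr, , drop = FALSE], yy[tr])
    pred_cv[!tr] <- as.vector(cbind(1, X[!tr, , drop = FALSE]) %*% bcv)
  }
  r2_cv <- 1 - sum((yy - pred_cv)^2) / sum((yy - mean(yy))^2)

  coefs <- tibble(
    lag = rep(lag_seq, each = length(chans)),
    channel = rep(chans, length(lag_seq)),
    estimate = as.vector(beta[-1])
  )
  structure(list(coefficients = coefs, intercept = beta[1], r2 = r2,
                 r2_cv = r2_cv, fitted = fitted, lags = lags, ridge = ridge),
            class = "distributed_lag_model")
}

#' Detect lick-bout onsets
#'
#' A bout onset is the first lick after at least `quiet_gap` seconds
#' without licks, provided at least `min_licks` licks follow within
#' `bout_window` seconds.
#'
#' @param lick_times Sorted lick timestamps (s).
#' @param quiet_gap Required lick-free gap before an onset (s).
#' @param min_licks Minimum licks within `bout_window` to count as a bout.
#' @param bout_window Seconds after the onset in which `min_licks` must
#'   occur.
#' @return Numeric vector of bout onset times.
#' @export
lick_bout_onsets <- function(lick_times, quiet_gap = 1, min_licks = 3,
                             bout_window = 1) {
  if (length(lick_times) == 0) return(numeric(0))
  lick_times <- sort(lick_times)
  gaps <- c(Inf, diff(lick_times))
  starts <- which(gaps >= quiet_gap)
  onset <- lick_times[starts]
  keep <- vapply(onset, function(t0) {
    sum(lick_times >= t0 & lick_times < t0 + bout_window) >= min_licks
  }, logical(1))
  onset[keep]
}

#' Decoupling of reward contingency and licking vigor per neuron
#'
#' Fits each neuron's per-trial response amplitude to (1) reward
#' contingency, (2) anticipatory licking, and (3) both plus their
#' interaction, and reports the loss in R^2 when either variable (and its
#' interaction) is omitted from the full model. Pure contingency encoders
#' show large `delta_r2_valence` and near-zero `delta_r2_licking`;
#' vigor encoders the converse. Both losses are non-negative by nesting.
#'
#' @param responses Per-trial response vector for one neuron, or a
#'   `neurons x trials` matrix.
#' @param contingency Per-trial sucrose probability P(S).
#' @param licks Per-trial anticipatory lick count (face-classifier
#'   estimates on spout-absent trials).
#' @param keep_interaction_in_reduced Keep the interaction term in the
#'   reduced models (off by default: a variable is dropped together with
#'   its interaction).
#' @return A tibble of class `decoupling_record`: `neuron`, `r2_full`,
#'   `delta_r2_valence`, `delta_r2_licking`.
#' @export
delta_r2_decoupling <- function(responses, contingency, licks,
                                keep_interaction_in_reduced = FALSE) {
  if (is.vector(responses)) responses <- matrix(responses, nrow = 1)
  m <- ncol(responses)
  if (m < 10) abort("need at least 10 trials")
  if (length(contingency) != m || length(licks) != m) {
    abort("regressor lengths do not match the trial count")
  }
  const_ps <- var(contingency) == 0
  const_lick <- var(licks) == 0
  if (const_ps) warn("constant contingency regressor: delta_r2_valence undefined")
  if (const_lick) warn("constant licking regressor: delta_r2_licking undefined")

  purrr::map_dfr(seq_len(nrow(responses)), function(i) {
    y <- responses[i, ]
    full <- lm(y ~ contingency * licks)
    r2_full <- r_squared(full)
    red_val <- if (keep_interaction_in_reduced) {
      lm(y ~ licks + contingency:licks)
    } else {
      lm(y ~ licks)
    }
    red_lick <- if (keep_interaction_in_reduced) {
      lm(y ~ contingency + contingency:licks)
    } else {
      lm(y ~ contingency)
    }
    tibble(
      neuron = i, r2_full = r2_full,
      delta_r2_valence = if (const_ps) NA_real_ else r2_full - r_squared(red_val),
      delta_r2_licking = if (const_lick) NA_real_ else r2_full - r_squared(red_lick)
    )
  }) |>
    structure(class = c("decoupling_record", class(tibble())))
}

#' Linear models of decoder accuracy against behavioral differences
#'
#' Fits session-level pairwise decoding accuracies (one per odor pair) to
#' (1) the range-normalized pairwise difference in anticipatory licking,
#' (2) the pairwise difference in sucrose contingency P(S), and (3) both
#' plus their interaction. The combined model's R^2 is at least that of
#' each single-variable model by nesting.
#'
#' @param accuracies Pairwise CV accuracies (e.g. 15 per session).
#' @param delta_lick Pairwise absolute difference in anticipatory licking;
#'   range-normalized to `[0, 1]` internally.
#' @param delta_ps Pairwise absolute difference in P(S).
#' @return A list of class `behavior_model_fits` with elements
#'   `lick_only`, `ps_only`, `combined` (each an `lm`), and a `summary`
#'   tibble (`model`, `r2`, coefficient estimates and p-values via
#'   [tidy()]).
#' @export
accuracy_behavior_models <- function(accuracies, delta_lick, delta_ps) {
  if (var(delta_lick) == 0 || var(delta_ps) == 0) {
    abort("zero-variance regressor")
  }
  rng <- range(delta_lick)
  dl <- (delta_lick - rng[1]) / diff(rng)
  df <- data.frame(accuracy = accuracies, delta_lick = dl, delta_ps = delta_ps)
  fits <- list(
    lick_only = lm(accuracy ~ delta_lick, df),
    ps_only = lm(accuracy ~ delta_ps, df),
    combined = lm(accuracy ~ delta_lick * delta_ps, df)
  )
  summary_tbl <- purrr::map_dfr(names(fits), function(nm) {
    tibble(model = nm, r2 = r_squared(fits[[nm]]))
  })
  structure(c(fits, list(summary = summary_tbl, data = df)),
            class = "behavior_model_fits")
}

#' @export
print.behavior_model_fits <- function(x, ...) {
  cat("<behavior_model_fits>\n")
  print(x$summary)
  invisible(x)
}
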