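#' Moving-baseline estimation with a Gaussian mixture model
#'
#' Estimates the slowly drifting baseline fluorescence of one neuron by
#' fitting a two-component Gaussian mixture inside a moving window
#' (2500 frames = 500 s at 5 Hz by default) and taking the mean of the
#' lower-mean component -- the "quiet" fluorescence between transients. The
#' mixture is refitted every `stride` frames on a window centered on the
#' evaluation point (truncated at the edges) and interpolated linearly in
#' between.
#'
#' @param trace Positive numeric vector of raw fluorescence for one neuron.
#' @param window_frames Moving-window length in frames.
#' @param n_components Mixture components; the lowest-mean component is the
#'   baseline.
#' @param stride Frames between mixture refits (interpolated in between).
#' @return Numeric vector of per-frame baseline estimates, same length and
#'   strictly positive.
#' @importFrom mclust Mclust mclustBIC
#' @export
#' @examples
#' tr <- 50 + rnorm(3000, 0, 0.2)
#' b <- estimate_moving_baseline(tr, window_frames = 500)
#' range(b)
estimate_moving_baseline <- function(trace, window_frames = 2500,
                                     n_components = 2, stride = 100) {
  if (any(!is.finite(trace))) abort("`trace` contains non-finite values")
  n <- length(trace)
  if (n < window_frames / 2) {
    abort("`trace` must be at least half the window length")
  }
  half <- floor(window_frames / 2)
  centers <- unique(c(seq(1, n, by = stride), n))

  fit_window <- function(c0) {
    lo <- max(1, c0 - half)
    hi <- min(n, c0 + half)
    x <- trace[lo:hi]
    if (sd(x) < 1e-12) return(mean(x))
    fit <- tryCatch(
      suppressWarnings(Mclust(x, G = n_components, modelNames = "V",
                              verbose = FALSE)),
      error = function(e) NULL
    )
    if (is.null(fit) || is.null(fit$parameters$mean)) return(median(x))
    min(fit$parameters$mean)
  }

  b_at <- vapply(centers, fit_window, numeric(1))
  baseline <- approx(centers, b_at, xout = seq_len(n), rule = 2)$y
  pmax(baseline, .Machine$double.eps)
}

#' Normalized fluorescence change dF/F
#'
#' Elementwise \eqn{(F_t - F_{baseline}) / F_{baseline}}.
#'
#' @param trace Raw fluorescence vector or `neurons x frames` matrix.
#' @param baseline Matching baseline (vector, matrix, or per-neuron vector
#'   recycled across frames).
#' @return dF/F with the same shape as `trace`.
#' @export
#' @examples
#' compute_dff(120, 100)
compute_dff <- function(trace, baseline) {
  if (any(baseline <= 0)) abort("`baseline` must be strictly positive")
  if (is.matrix(trace) && !is.matrix(baseline) &&
      length(baseline) == nrow(trace)) {
    baseline <- matrix(baseline, nrow(trace), ncol(trace))
  }
  if (!identical(dim(trace), dim(baseline)) &&
      length(trace) != length(baseline)) {
    abort("`trace` and `baseline` shapes do not match")
  }
  (trace - baseline) / baseline
}

#' Session-level dF/F
#'
#' Runs [estimate_moving_baseline()] and [compute_dff()] over every neuron
#' of a session's fluorescence matrix.
#'
#' @param session A `simulated_session` (or any list with a
#'   `fluorescence` matrix).
#' @param ... Passed to [estimate_moving_baseline()].
#' @return A `neurons x frames` dF/F matrix carrying the session's
#'   `frame_times`/`frame_rate` attributes.
#' @export
session_dff <- function(session, ...) {
  fluo <- session$fluorescence
  base <- t(apply(fluo, 1, estimate_moving_baseline, ...))
  dff <- compute_dff(fluo, base)
  structure(dff, frame_times = attr(fluo, "frame_times"),
            frame_rate = attr(fluo, "frame_rate"))
}

#' Align dF/F traces into a trial tensor
#'
#' Slices each trial's window from `pre_s` before to `post_s` after odor
#' onset. Frame 0 of the time axis is the first frame at or after odor
#' onset; windows are half-open so a trial spans
#' `pre_s * rate + post_s * rate` frames.
#'
#' @param dff `neurons x frames` dF/F matrix with a `frame_times`
#'   attribute (e.g. from [session_dff()]), or a plain matrix plus
#'   `frame_times`.
#' @param trials A [build_trial_table()] table.
#' @param pre_s Seconds before odor onset.
#' @param post_s Seconds after odor onset.
#' @param frame_times Frame start times; defaults to the attribute on `dff`.
#' @return A `dff_tensor`: 3-d array `neurons x trials x frames` with
#'   attributes `time_axis` (s relative to onset), `trials` (the trial
#'   table), and `frame_rate`.
#' @export
align_trials <- function(dff, trials, pre_s = 2, post_s = 8,
                         frame_times = attr(dff, "frame_times")) {
  stopifnot(inherits(trials, "trial_table"))
  if (is.null(frame_times)) abort("`frame_times` required to align trials")
  rate <- round(1 / diff(frame_times[1:2]))
  n_pre <- round(pre_s * rate)
  n_post <- round(post_s * rate)
  onset <- findInterval(trials$odor_on - 1e-9, frame_times) + 1L
  lo <- onset - n_pre
  hi <- onset + n_post - 1L
  bad <- which(lo < 1 | hi > ncol(dff))
  if (length(bad)) {
    abort(sprintf("trial %d window [%g, %g] s lies outside the recording",
                  bad[1], trials$odor_on[bad[1]] - pre_s,
                  trials$odor_on[bad[1]] + post_s))
  }
  tensor <- array(NA_real_, c(nrow(dff), nrow(trials), n_pre + n_post))
  for (i in seq_len(nrow(trials))) {
    tensor[, i, ] <- dff[, lo[i]:hi[i], drop = FALSE]
  }
  structure(tensor,
    class = "dff_tensor",
    time_axis = (seq_len(n_pre + n_post) - n_pre - 1) / rate,
    trials = trials, frame_rate = rate
  )
}

#' @export
print.dff_tensor <- function(x, ...) {
  d <- dim(x)
  ta <- attr(x, "time_axis")
  cat(sprintf("<dff_tensor> %d neurons x %d trials x %d frames, t = [%g, %g] s\n",
              d[1], d[2], d[3], min(ta), max(ta)))
  invisible(x)
}

#' Windowed per-trial response features
#'
#' Averages dF/F over a half-open time window `[t0, t1)` for every neuron
#' and trial, optionally Z-scoring each neuron across the selected trials.
#' Zero-variance neurons cannot be Z-scored; they are dropped with a
#' message and recorded in the `excluded` attribute.
#'
#' @param tensor A [align_trials()] tensor.
#' @param window `[t0, t1)` in seconds relative to odor onset.
#' @param zscore Standardize each neuron across the selected trials.
#' @param trials Optional integer subset of trials.
#' @return `neurons x trials` matrix (rows dropped if excluded); attribute
#'   `excluded` lists dropped neuron indices.
#' @export
window_features <- function(tensor, window = c(1, 2), zscore = FALSE,
                            trials = NULL) {
  ta <- attr(tensor, "time_axis")
  idx <- frames_in_window(ta, window)
  if (!length(idx)) abort("empty window: no frames in [t0, t1)")
  if (is.null(trials)) trials <- seq_len(dim(tensor)[2])
  sub <- tensor[, trials, idx, drop = FALSE]
  feat <- apply(sub, c(1, 2), mean)
  excluded <- integer(0)
  if (zscore) {
    sds <- apply(feat, 1, sd)
    excluded <- which(sds == 0)
    if (length(excluded)) {
      inform(sprintf("window_features: excluded %d zero-variance neuron(s): %s",
                     length(excluded), paste(excluded, collapse = ", ")))
      feat <- feat[-excluded, , drop = FALSE]
      sds <- sds[-excluded]
    }
    feat <- (feat - rowMeans(feat)) / sds
  }
  structure(feat, excluded = excluded)
}

#' Per-neuron odor response magnitudes (ddF/F)
#'
#' For each neuron and odor, the trial-averaged dF/F in the last second of
#' the odor (`[1, 2)` s) minus the trial-averaged dF/F in the 2 s before
#' odor onset (`[-2, 0)` s). The `scaled` matrix divides each neuron's row
#' by its largest positive entry, so the per-neuron maximum is exactly 1;
#' neurons with no positive response cannot be scaled and their rows are
#' `NA` (flagged in `undefined_scaled`).
#'
#' @param tensor A [align_trials()] tensor covering at least `[-2, 2)` s.
#' @return A list of class `response_magnitude`: `ddff` and `scaled`
#'   (`neurons x odors` matrices, columns in scheme odor order),
#'   `undefined_scaled` (neuron indices), and `odors`.
#' @export
delta_delta_f <- function(tensor) {
  ta <- attr(tensor, "time_axis")
  if (min(ta) > -2 + 1e-9 || max(ta) < 2 - 1/attr(tensor, "frame_rate") - 1e-9) {
    abort("tensor must cover [-2, 2) s around odor onset")
  }
  trials <- attr(tensor, "trials")
  scheme <- attr(trials, "scheme")
  odors <- scheme$odor
  late <- frames_in_window(ta, c(1, 2))
  pre <- frames_in_window(ta, c(-2, 0))
  n <- dim(tensor)[1]
  ddff <- matrix(NA_real_, n, length(odors), dimnames = list(NULL, odors))
  for (o in odors) {
    tr <- which(trials$odor == o)
    per_trial <- apply(tensor[, tr, late, drop = FALSE], c(1, 2), mean) -
      apply(tensor[, tr, pre, drop = FALSE], c(1, 2), mean)
    ddff[, o] <- rowMeans(per_trial)
  }
  maxpos <- apply(ddff, 1, function(r) if (any(r > 0)) max(r) else NA_real_)
  undefined <- which(is.na(maxpos))
  if (length(undefined)) {
    inform(sprintf(
      "delta_delta_f: %d neuron(s) with no positive ddF/F left unscaled",
      length(undefined)))
  }
  scaled <- ddff / maxpos
  structure(list(ddff = ddff, scaled = scaled,
                 undefined_scaled = undefined, odors = odors),
            class = "response_magnitude")
}
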