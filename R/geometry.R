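# Population response geometry: pairwise distance trajectories and
# participation-ratio dimensionality.

#' Normalized pairwise Euclidean distance trajectories
#'
#' For each odor pair and frame, the Euclidean distance between the two
#' odors' baseline-subtracted, trial-averaged population vectors. Each
#' trial's pre-odor mean (`[-2, 0)` s, per neuron) is subtracted before
#' trial-averaging; distances are normalized by the maximum over all pairs
#' and frames, so the global maximum is exactly 1.
#'
#' @param tensor A [align_trials()] tensor covering the pre-odor baseline.
#' @return A tibble of class `distance_trajectories`: `pair`, `odor_1`,
#'   `odor_2`, `time`, `distance` (in `[0, 1]`); attribute
#'   `normalization` holds the raw global maximum.
#' @export
distance_trajectories <- function(tensor) {
  ta <- attr(tensor, "time_axis")
  trials <- attr(tensor, "trials")
  scheme <- attr(trials, "scheme")
  pre <- frames_in_window(ta, c(-2, 0))
  if (!length(pre)) abort("tensor must cover the 2 s pre-odor baseline")
  n <- dim(tensor)[1]; n_frames <- dim(tensor)[3]

  # baseline-subtract per trial, then trial-average per odor
  means <- lapply(scheme$odor, function(o) {
    tr <- which(trials$odor == o)
    sub <- tensor[, tr, , drop = FALSE]
    base <- apply(sub[, , pre, drop = FALSE], c(1, 2), mean)
    sub <- sweep(sub, c(1, 2), base)
    apply(sub, c(1, 3), mean) # neurons x frames
  })
  names(means) <- scheme$odor

  cmb <- utils::combn(scheme$odor, 2)
  role <- setNames(scheme$role, scheme$odor)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    d <- sqrt(colSums((means[[cmb[1, k]]] - means[[cmb[2, k]]])^2))
    tibble(
      pair = paste(role[cmb[, k]], collapse = " vs "),
      odor_1 = cmb[1, k], odor_2 = cmb[2, k], time = ta, distance = d
    )
  })
  out <- dplyr::bind_rows(rows)
  norm <- max(out$distance)
  if (norm > 0) out$distance <- out$distance / norm
  attr(out, "normalization") <- norm
  class(out) <- c("distance_trajectories", class(out))
  out
}

#' Participation ratio from covariance eigenvalues
#'
#' @param eigenvalues Non-negative eigenvalues of a covariance matrix.
#' @return `(sum(lambda))^2 / sum(lambda^2)`.
#' @export
#' @examples
#' pr_from_eigenvalues(c(2, 1, 1)) # 16/6
pr_from_eigenvalues <- function(eigenvalues) {
  s <- sum(eigenvalues)
  q <- sum(eigenvalues^2)
  if (q == 0) abort("zero-variance data: participation ratio undefined")
  s^2 / q
}

#' Participation-ratio dimensionality of population activity
#'
#' Effective dimensionality of a `samples x neurons` activity matrix: the
#' square of the sum of the eigenvalues of the neuron covariance matrix
#' divided by the sum of their squares. The value lies in `[1, n]`: 1 when
#' a single principal component carries all variance, `n` when all
#' components contribute equally. Scale-invariant and (through the
#' unbiased covariance) independent of sample count up to estimation
#' noise.
#'
#' @param data `samples x neurons` matrix (e.g. all trial-aligned dF/F
#'   frames concatenated across trials).
#' @return A list of class `pr_result`: `pr`, `eigenvalues`, `n_neurons`,
#'   `n_samples`.
#' @export
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' participation_ratio(x)$pr
participation_ratio <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2) abort("need at least 2 samples")
  ev <- eigen(cov(data), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0) # clip numerical negatives
  structure(list(pr = pr_from_eigenvalues(ev), eigenvalues = ev,
                 n_neurons = ncol(data), n_samples = nrow(data)),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("<pr_result> PR = %.3f over %d neurons (%d samples)\n",
              x$pr, x$n_neurons, x$n_samples))
  invisible(x)
}

#' Subsampled participation ratio
#'
#' Repeatedly samples `k` neurons without replacement and averages their
#' participation ratio, removing the dependence of PR on population size
#' when comparing populations of different sizes.
#'
#' @param data `samples x neurons` matrix.
#' @param k Neurons per subsample.
#' @param n_resamples Number of subsamples.
#' @param seed Integer seed.
#' @return A list of class `pr_result`: `pr` (mean over resamples),
#'   `per_resample`, `k`, `n_resamples`.
#' @export
subsampled_pr <- function(data, k = 15, n_resamples = 1000, seed = NULL) {
  data <- as.matrix(data)
  if (k > ncol(data)) abort("`k` exceeds the population size")
  if (!is.null(seed)) set.seed(seed)
  if (k == ncol(data)) {
    base <- participation_ratio(data)
    prs <- rep(base$pr, n_resamples)
  } else {
    prs <- vapply(seq_len(n_resamples), function(r) {
      participation_ratio(data[, sample(ncol(data), k), drop = FALSE])$pr
    }, numeric(1))
  }
  structure(list(pr = mean(prs), per_resample = prs, k = k,
                 n_resamples = n_resamples, n_neurons = ncol(data),
                 n_samples = nrow(data)),
            class = "pr_result")
}

#' Flatten a trial tensor into a samples x neurons matrix
#'
#' Concatenates all trial-aligned frames across trials -- the sample set
#' used for dimensionality analysis. A trial-averaged variant (one sample
#' per odor x frame) is available via `trial_average`.
#'
#' @param tensor A [align_trials()] tensor.
#' @param trial_average Average over trials within odor first.
#' @return A `samples x neurons` matrix.
#' @export
tensor_samples <- function(tensor, trial_average = FALSE) {
  d <- dim(tensor)
  if (!trial_average) {
    return(t(matrix(tensor, nrow = d[1])))
  }
  trials <- attr(tensor, "trials")
  odors <- unique(trials$odor)
  do.call(rbind, lapply(odors, function(o) {
    t(apply(tensor[, trials$odor == o, , drop = FALSE], c(1, 3), mean))
  }))
}
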