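#' Frame-wise rank-sum responsiveness test
#'
#' For one odor, compares dF/F at each frame of the response window against
#' the pooled distribution of pre-odor dF/F (all frames in `[-2, 0)` s
#' across the odor's trials) with a two-sided Wilcoxon rank sum test. With
#' 30 trials at 5 Hz the pooled baseline holds 300 samples and the odor
#' period contributes 10 tested frames. The direction of each frame's
#' effect is the sign of the median difference.
#'
#' @param tensor A [align_trials()] tensor.
#' @param odor Odor label to test.
#' @param window Response window `[t0, t1)` in seconds relative to odor
#'   onset; the 2 s odor period by default. A US-locked window (e.g.
#'   `us_time - odor_on + c(0, 2)`) supports outcome-responsiveness tests.
#' @return A tibble `neuron`, `frame`, `time`, `p`, `direction` (+1/-1/0).
#' @export
framewise_rank_test <- function(tensor, odor, window = c(0, 2)) {
  trials <- attr(tensor, "trials")
  ta <- attr(tensor, "time_axis")
  tr <- which(trials$odor == odor)
  if (length(tr) < 2) abort(sprintf("need >= 2 trials of odor '%s'", odor))
  test_f <- frames_in_window(ta, window)
  pre_f <- frames_in_window(ta, c(-2, 0))
  n <- dim(tensor)[1]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pool <- as.vector(tensor[i, tr, pre_f])
    p <- numeric(length(test_f))
    dir <- numeric(length(test_f))
    for (k in seq_along(test_f)) {
      x <- tensor[i, tr, test_f[k]]
      if (length(unique(c(x, pool))) == 1) {
        warn("all values tied; p set to 1")
        p[k] <- 1; dir[k] <- 0
      } else {
        p[k] <- suppressWarnings(
          wilcox.test(x, pool, exact = FALSE)$p.value
        )
        dir[k] <- sign(median(x) - median(pool))
      }
    }
    out[[i]] <- tibble(neuron = i, frame = seq_along(test_f),
                       time = ta[test_f], p = p, direction = dir)
  }
  dplyr::bind_rows(out)
}

#' Holm-Bonferroni step-down rejections
#'
#' Standard Holm step-down procedure controlling the familywise error rate
#' at `alpha` (via `stats::p.adjust(method = "holm")`). The rejected set is
#' always a prefix of the sorted p-values.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha FWER level.
#' @return Logical rejection flags aligned with `pvals`.
#' @export
#' @examples
#' holm_bonferroni(c(0.001, 0.2, 0.3))
holm_bonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = "holm") <= alpha
}

#' Classify per-neuron odor responsiveness
#'
#' Applies Holm correction within each neuron's family of tested frames and
#' calls a neuron responsive to the odor when at least `min_frames` frames
#' (not necessarily consecutive) are significant. Direction is the majority
#' sign among significant frames (`"excited"`/`"inhibited"`); an exact tie
#' is labelled `"mixed"` and excluded from direction-specific counts.
#'
#' @param framewise Output of [framewise_rank_test()].
#' @param alpha FWER level per neuron x odor family.
#' @param min_frames Minimum significant frames to call responsiveness.
#' @return A tibble `neuron`, `significant_frames`, `responsive`,
#'   `direction` (`excited`/`inhibited`/`mixed`/`none`).
#' @export
classify_responsiveness <- function(framewise, alpha = 0.05, min_frames = 4L) {
  framewise |>
    dplyr::group_by(.data$neuron) |>
    dplyr::summarise(
      significant_frames = sum(holm_bonferroni(.data$p, alpha)),
      n_pos = sum(holm_bonferroni(.data$p, alpha) & .data$direction > 0),
      n_neg = sum(holm_bonferroni(.data$p, alpha) & .data$direction < 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      responsive = .data$significant_frames >= min_frames,
      direction = dplyr::case_when(
        !.data$responsive ~ "none",
        .data$n_pos > .data$n_neg ~ "excited",
        .data$n_neg > .data$n_pos ~ "inhibited",
        TRUE ~ "mixed"
      )
    ) |>
    dplyr::select("neuron", "significant_frames", "responsive", "direction")
}

#' Responsiveness of every neuron to every odor
#'
#' Convenience wrapper running [framewise_rank_test()] and
#' [classify_responsiveness()] across the odor panel.
#'
#' @inheritParams framewise_rank_test
#' @inheritParams classify_responsiveness
#' @return A tibble with one row per neuron x odor.
#' @export
responsiveness_table <- function(tensor, window = c(0, 2), alpha = 0.05,
                                 min_frames = 4L) {
  odors <- attr(attr(tensor, "trials"), "scheme")$odor
  purrr::map_dfr(odors, function(o) {
    classify_responsiveness(framewise_rank_test(tensor, o, window),
                            alpha = alpha, min_frames = min_frames) |>
      dplyr::mutate(odor = o, .after = "neuron")
  })
}

#' Cross-day response transfer of matched neurons
#'
#' Given responsiveness calls for matched neurons in two epochs -- for
#' example US-locked responses on day 1 and cue-locked responses on day 3
#' -- reports the fraction of matched neurons responsive in both epochs
#' with the same direction, and the per-neuron change in windowed response
#' magnitude.
#'
#' @param day_a,day_b Tibbles with columns `neuron`, `responsive`,
#'   `direction`, and `magnitude` (windowed response magnitude, e.g. a
#'   ddF/F column). `day_a` is the earlier epoch.
#' @param pairs Tibble with columns `neuron_a`, `neuron_b` giving the
#'   one-to-one match between the two sessions.
#' @return A list of class `transfer_result`: `fraction` (responsive in
#'   both epochs, same direction), `n_pairs`, and `per_neuron` tibble with
#'   `magnitude_change = day_b - day_a`.
#' @export
cross_day_transfer <- function(day_a, day_b, pairs) {
  if (nrow(pairs) == 0) abort("`pairs` is empty")
  if (anyDuplicated(pairs$neuron_a) || anyDuplicated(pairs$neuron_b)) {
    abort("`pairs` must be a one-to-one matching")
  }
  a <- day_a[match(pairs$neuron_a, day_a$neuron), ]
  b <- day_b[match(pairs$neuron_b, day_b$neuron), ]
  both <- a$responsive & b$responsive &
    a$direction == b$direction & a$direction %in% c("excited", "inhibited")
  per_neuron <- tibble(
    neuron_a = pairs$neuron_a, neuron_b = pairs$neuron_b,
    transferred = both,
    magnitude_change = b$magnitude - a$magnitude
  )
  structure(list(fraction = mean(both), n_pairs = nrow(pairs),
                 per_neuron = per_neuron),
            class = "transfer_result")
}
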