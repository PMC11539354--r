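#' Simulate licking, locomotion, eye and face-feature behavior
#'
#' Generates the behavioral channels of a conditioning session on the
#' imaging frame clock (5 Hz by default). Licks are an inhomogeneous point
#' process: a low baseline rate, an anticipatory ramp during
#' sucrose-contingent odors whose gain follows a logistic learning curve
#' across trials, a consumption burst at sucrose delivery, and near-complete
#' suppression while the lick spout is retracted. Locomotion slows and the
#' eye partially closes around airpuff cues; the three face-feature channels
#' (tongue-tip confidence, mouth-corner confidence, upper-lower lip
#' distance) are noisy deterministic functions of the instantaneous lick
#' state, mimicking video keypoint readouts.
#'
#' With `learning_rate = 0` the anticipatory gain is identically zero (a
#' never-learning animal), so lick rates are statistically equal across
#' odors.
#'
#' @param trials A [build_trial_table()] table.
#' @param scheme The matching [make_odor_scheme()] scheme.
#' @param learning_rate Steepness (per trial) of the logistic gain ramp.
#' @param learning_midpoint Trial at which the gain reaches half maximum.
#' @param asymptote Peak anticipatory lick rate (licks/s) of a trained
#'   animal during a 100%-sucrose odor.
#' @param base_rate Baseline lick rate (licks/s) with the spout present.
#' @param burst_rate Consumption lick rate (licks/s) after sucrose.
#' @param feature_noise_sd Gaussian SD of the face-feature channels.
#' @param frame_rate Frames per second of the behavior clock.
#' @param tail_s Seconds of recording kept after the last trial.
#' @param seed Integer seed.
#' @return A list of class `behavior_trace`: `lick_times` (s),
#'   `frame_times` (s, frame start times), `lick_count` (licks per frame),
#'   `lick_state` (0/1 per frame), `locomotion`, `eye_area`,
#'   `face_features` (frames x 3 matrix), `spout_in` (logical per frame),
#'   and `anticipatory_gain` (per trial).
#' @export
simulate_behavior <- function(trials, scheme,
                              learning_rate = 0.05,
                              learning_midpoint = 60,
                              asymptote = 8,
                              base_rate = 0.2,
                              burst_rate = 8,
                              feature_noise_sd = 0.15,
                              frame_rate = 5,
                              tail_s = 10,
                              seed = NULL) {
  stopifnot(inherits(trials, "trial_table"), learning_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  paradigm <- attr(trials, "paradigm")
  n_tr <- nrow(trials)
  duration <- max(trials$us_time) + tail_s
  n_frames <- ceiling(duration * frame_rate)
  ft <- (seq_len(n_frames) - 1) / frame_rate
  dt <- 1 / frame_rate

  gain <- if (learning_rate == 0) {
    rep(0, n_tr)
  } else {
    plogis(learning_rate * (trials$trial_index - learning_midpoint))
  }

  value <- odor_value(scheme)
  rate <- rep(base_rate, n_frames)
  spout_in <- rep(TRUE, n_frames)

  for (i in seq_len(n_tr)) {
    on <- trials$odor_on[i]; us <- trials$us_time[i]
    v <- value[[trials$odor[i]]]
    # anticipatory ramp: builds from 0.5 s into the odor until US time
    if (v > 0) {
      idx <- which(ft >= on + 0.5 & ft < us)
      if (length(idx)) {
        ramp <- (ft[idx] - (on + 0.5)) / (us - (on + 0.5))
        rate[idx] <- rate[idx] + gain[i] * v * asymptote * ramp
      }
    }
    if (trials$us_type[i] == "sucrose") {
      idx <- which(ft >= us & ft < us + 2)
      rate[idx] <- pmax(rate[idx], burst_rate)
    }
    if (!trials$spout_present[i]) {
      # spout retracts 0.2 s before odor and returns 0.1 s before the
      # earliest possible sucrose time
      idx <- which(ft >= on - 0.2 & ft < trials$odor_off[i] + 1.0)
      spout_in[idx] <- FALSE
    }
  }
  rate[!spout_in] <- rate[!spout_in] * 0.01

  lick_count <- rpois(n_frames, rate * dt)
  lick_times <- unlist(lapply(which(lick_count > 0), function(k) {
    sort(ft[k] + runif(lick_count[k], 0, dt))
  }))
  if (is.null(lick_times)) lick_times <- numeric(0)
  lick_state <- as.numeric(lick_count > 0)

  # locomotion: smooth positive speed, halved around airpuff cues
  loco_drive <- rep(1, n_frames)
  eye <- rep(1, n_frames)
  if (paradigm == "exp1") {
    puff_odors <- scheme$odor[scheme$contingency == "P"]
    for (i in which(trials$odor %in% puff_odors)) {
      idx <- which(ft >= trials$odor_on[i] & ft < trials$us_time[i] + 2)
      loco_drive[idx] <- loco_drive[idx] * (1 - 0.5 * gain[i])
      eye[idx] <- eye[idx] * (1 - 0.3 * gain[i])
    }
  }
  ar <- stats::filter(rnorm(n_frames, 0, 0.3), 0.9, method = "recursive")
  locomotion <- pmax(0, 2 * loco_drive + as.numeric(ar))
  eye_area <- pmax(0.1, eye + rnorm(n_frames, 0, 0.05))

  smooth_state <- as.numeric(stats::filter(lick_state, rep(1 / 2, 2), sides = 1))
  smooth_state[is.na(smooth_state)] <- lick_state[is.na(smooth_state)]
  face <- cbind(
    tongue_conf = 0.05 + 0.9 * smooth_state + rnorm(n_frames, 0, feature_noise_sd),
    mouth_conf = 0.20 + 0.7 * smooth_state + rnorm(n_frames, 0, feature_noise_sd),
    lip_dist = 1.0 + 2.0 * smooth_state + rnorm(n_frames, 0, 2 * feature_noise_sd)
  )

  structure(
    list(
      lick_times = lick_times, frame_times = ft, lick_count = lick_count,
      lick_state = lick_state, locomotion = locomotion, eye_area = eye_area,
      face_features = face, spout_in = spout_in, anticipatory_gain = gain,
      frame_rate = frame_rate
    ),
    class = "behavior_trace"
  )
}

#' Per-trial anticipatory lick counts
#'
#' Counts licks inside an analysis window relative to odor onset for every
#' trial. The default window for the switch paradigm is the 2 s odor period;
#' for the lick-spout paradigm the convention is the last 0.5 s of odor plus
#' the first 0.5 s of the trace delay (`window = c(1.5, 2.5)`). For
#' spout-removed trials, estimated licks from a face-feature classifier can
#' be substituted via `estimated`.
#'
#' @param behavior A [simulate_behavior()] trace (or compatible list with
#'   `lick_times`).
#' @param trials A [build_trial_table()] table.
#' @param window Numeric `[t0, t1)` in seconds relative to odor onset.
#' @param estimated Optional per-frame lick probability (same clock as
#'   `behavior$frame_times`) used for trials with `spout_present == FALSE`.
#' @return A tibble `trial_index`, `odor`, `licks`.
#' @export
anticipatory_licks <- function(behavior, trials, window = c(0, 2), estimated = NULL) {
  counts <- vapply(seq_len(nrow(trials)), function(i) {
    lo <- trials$odor_on[i] + window[1]
    hi <- trials$odor_on[i] + window[2]
    if (!trials$spout_present[i] && !is.null(estimated)) {
      idx <- which(behavior$frame_times >= lo - 1e-9 & behavior$frame_times < hi - 1e-9)
      sum(estimated[idx])
    } else {
      sum(behavior$lick_times >= lo & behavior$lick_times < hi)
    }
  }, numeric(1))
  tibble(trial_index = trials$trial_index, odor = trials$odor, licks = counts)
}
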