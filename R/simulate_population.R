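#' Simulate per-trial response amplitudes from ground-truth encoding
#'
#' The linear encoding model behind every simulated neuron: the response
#' amplitude of neuron \eqn{n} on trial \eqn{t} is
#' \deqn{a_{nt} = s_n (w_{id,n}^\top \mathrm{onehot}(o_t) + w_{val,n}
#'   v(o_t) + w_{lick,n} \ell_t) + \epsilon_{nt}}
#' where \eqn{v(o)} is the odor's contingency value (see [odor_value()]),
#' \eqn{\ell_t} the standardized anticipatory lick regressor for the trial,
#' \eqn{s_n \in \{+1, -1\}} the response sign, and
#' \eqn{\epsilon_{nt} \sim N(0, \sigma_n)} trial noise.
#'
#' @param truth A [make_ground_truth()] tibble.
#' @param trials A [build_trial_table()] table.
#' @param behavior A [simulate_behavior()] trace, required only when any
#'   neuron has nonzero `w_lick`; `NULL` otherwise.
#' @param lick_window Window (s relative to odor onset) for the
#'   anticipatory-lick regressor; defaults to the paradigm's analysis bin
#'   (odor period for exp1, last 0.5 s odor + first 0.5 s delay for exp2).
#' @param seed Integer seed.
#' @return A `neurons x trials` numeric matrix of response amplitudes, with
#'   the standardized lick regressor attached as attribute `lick_regressor`.
#' @export
simulate_population <- function(truth, trials, behavior = NULL,
                                lick_window = NULL, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(trials, "trial_table"))
  if (!is.null(seed)) set.seed(seed)
  scheme <- attr(trials, "scheme")
  if (any(lengths(truth$w_identity) != 6)) {
    abort("identity weights must have length 6 (one per odor)")
  }
  n <- nrow(truth); m <- nrow(trials)
  onehot <- outer(scheme$odor, trials$odor, "==") * 1 # 6 x trials
  W <- do.call(rbind, truth$w_identity) # n x 6
  value <- odor_value(scheme)[trials$odor]

  lick_reg <- rep(0, m)
  if (any(truth$w_lick != 0)) {
    if (is.null(behavior)) abort("`behavior` is required when any neuron has w_lick != 0")
    if (is.null(lick_window)) {
      lick_window <- if (attr(trials, "paradigm") == "exp1") c(0, 2) else c(1.5, 2.5)
    }
    licks <- anticipatory_licks(behavior, trials, lick_window)$licks
    lick_reg <- if (sd(licks) > 0) (licks - mean(licks)) / sd(licks) else licks * 0
  }

  det <- W %*% onehot +
    truth$w_valence %*% t(value) +
    truth$w_lick %*% t(lick_reg)
  amp <- truth$sign * det + matrix(rnorm(n * m, 0, truth$noise_sd), n, m)
  dimnames(amp) <- list(NULL, NULL)
  attr(amp, "lick_regressor") <- lick_reg
  amp
}

#' Render raw fluorescence traces from trial amplitudes
#'
#' Converts a `neurons x trials` amplitude matrix into raw fluorescence at
#' the imaging frame rate. Each trial's amplitude enters as an instantaneous
#' rise at the odor-onset frame convolved with a single-exponential decay
#' kernel \eqn{\exp(-t/\tau)}, superimposed on the neuron's baseline level,
#' a slow drift (linear slope plus sinusoid), and Gaussian frame noise.
#' Fluorescence is clipped at a small positive epsilon; clipping is
#' reported via a message.
#'
#' @param amplitudes `neurons x trials` matrix (fluorescence units).
#' @param truth The matching [make_ground_truth()] tibble (baseline, drift,
#'   noise and kernel parameters).
#' @param trials The matching [build_trial_table()] table.
#' @param frame_rate Frames per second (5 for the imaging clock).
#' @param duration_s Total recording length; defaults to covering the last
#'   trial plus 10 s.
#' @param us_amplitude Optional `neurons x trials` matrix of extra
#'   transients injected at US time (used to make neurons
#'   sucrose-responsive independently of the cue).
#' @param eps Positivity floor for the clipped fluorescence.
#' @param seed Integer seed.
#' @return A `neurons x frames` fluorescence matrix with attributes
#'   `frame_times` and `frame_rate`.
#' @export
render_calcium <- function(amplitudes, truth, trials, frame_rate = 5,
                           duration_s = NULL, us_amplitude = NULL,
                           eps = 1e-3, seed = NULL) {
  stopifnot(frame_rate > 0, nrow(amplitudes) == nrow(truth),
            ncol(amplitudes) == nrow(trials))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration_s)) duration_s <- max(trials$us_time) + 10
  n_frames <- ceiling(duration_s * frame_rate)
  ft <- (seq_len(n_frames) - 1) / frame_rate
  n <- nrow(amplitudes)

  # onset frame = first frame whose start time >= event time
  onset_frame <- findInterval(trials$odor_on - 1e-9, ft) + 1L
  us_frame <- findInterval(trials$us_time - 1e-9, ft) + 1L

  F <- matrix(0, n, n_frames)
  klen <- ceiling(8 * max(truth$kernel_tau) * frame_rate)
  for (i in seq_len(n)) {
    kern <- exp(-(0:klen) / (truth$kernel_tau[i] * frame_rate))
    sig <- numeric(n_frames + klen + 1)
    for (j in seq_len(ncol(amplitudes))) {
      k0 <- onset_frame[j]
      sig[k0:(k0 + klen)] <- sig[k0:(k0 + klen)] + amplitudes[i, j] * kern
      if (!is.null(us_amplitude) && us_amplitude[i, j] != 0) {
        k1 <- us_frame[j]
        sig[k1:(k1 + klen)] <- sig[k1:(k1 + klen)] + us_amplitude[i, j] * kern
      }
    }
    drift <- truth$drift_slope[i] * ft +
      truth$drift_sin_amp[i] * sin(2 * pi * ft / truth$drift_sin_period[i])
    F[i, ] <- truth$baseline_level[i] + drift + sig[seq_len(n_frames)] +
      rnorm(n_frames, 0, truth$fluo_noise_sd[i])
  }
  n_clip <- sum(F < eps)
  if (n_clip > 0) {
    inform(sprintf("render_calcium: clipped %d frames at %g", n_clip, eps))
    F[F < eps] <- eps
  }
  structure(F, frame_times = ft, frame_rate = frame_rate)
}

#' Simulate a complete session
#'
#' Convenience wrapper tying together [make_odor_scheme()],
#' [build_trial_table()], [simulate_behavior()], [make_ground_truth()],
#' [simulate_population()] and [render_calcium()] under a single seed.
#' Regenerating with the same configuration and seed is bit-identical.
#'
#' @param n_neurons Number of neurons.
#' @param paradigm `"exp1"` or `"exp2"`.
#' @param day Imaging day (exp1 contingencies switch on day 4).
#' @param n_blocks Trial blocks (30 for a standard session).
#' @param seed Integer root seed; named substreams are derived per stage.
#' @param class_probs,amp_scale,noise_sd,... passed to [make_ground_truth()].
#' @param learning_rate,asymptote passed to [simulate_behavior()].
#' @param frame_rate Imaging frame rate (Hz).
#' @return A list of class `simulated_session`: `fluorescence`
#'   (neurons x frames), `frame_times`, `behavior`, `trials`, `scheme`,
#'   `truth`, `amplitudes`, `frame_rate`, `seed`.
#' @export
#' @examples
#' s <- simulate_session(10, n_blocks = 2, seed = 1)
#' dim(s$fluorescence)
simulate_session <- function(n_neurons = 60, paradigm = c("exp1", "exp2"),
                             day = 3L, n_blocks = 30L, seed = 1L,
                             class_probs = c(identity = 0.35, valence = 0.25,
                                             vigor = 0.15, silent = 0.25),
                             amp_scale = 0.3, noise_sd = 0.1,
                             learning_rate = 0.05, asymptote = 8,
                             frame_rate = 5, ...) {
  paradigm <- match.arg(paradigm)
  scheme <- make_odor_scheme(paradigm, day = day)
  trials <- build_trial_table(scheme, n_blocks = n_blocks,
                              seed = derive_seed(seed, "trials"))
  behavior <- simulate_behavior(trials, scheme, learning_rate = learning_rate,
                                asymptote = asymptote, frame_rate = frame_rate,
                                seed = derive_seed(seed, "behavior"))
  truth <- make_ground_truth(n_neurons, class_probs = class_probs,
                             amp_scale = amp_scale, noise_sd = noise_sd,
                             seed = derive_seed(seed, "truth"), ...)
  # amplitudes are in dF/F units relative to baseline; convert to raw
  # fluorescence units per neuron for rendering
  amp <- simulate_population(truth, trials, behavior,
                             seed = derive_seed(seed, "population"))
  fluo <- render_calcium(amp * truth$baseline_level, truth, trials,
                         frame_rate = frame_rate,
                         duration_s = length(behavior$frame_times) / frame_rate,
                         seed = derive_seed(seed, "calcium"))
  structure(
    list(
      fluorescence = fluo, frame_times = attr(fluo, "frame_times"),
      behavior = behavior, trials = trials, scheme = scheme, truth = truth,
      amplitudes = amp, frame_rate = frame_rate, seed = seed
    ),
    class = "simulated_session"
  )
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf(
    "<simulated_session> %d neurons x %d frames @ %g Hz, %d trials (%s), seed %s\n",
    nrow(x$fluorescence), ncol(x$fluorescence), x$frame_rate,
    nrow(x$trials), attr(x$trials, "paradigm"), format(x$seed)
  ))
  invisible(x)
}
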