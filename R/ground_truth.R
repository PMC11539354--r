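#' Draw per-neuron ground-truth encoding parameters
#'
#' Each simulated neuron belongs to one encoder class and carries the latent
#' weights the downstream analyses try to recover:
#'
#' * `identity` -- tuned to individual odors (`w_identity` block nonzero),
#' * `valence` -- coupled to reward contingency (`w_valence` nonzero),
#' * `vigor` -- coupled to anticipatory lick rate (`w_lick` nonzero),
#' * `silent` -- all weights zero (pure noise).
#'
#' Weight magnitudes are expressed in the same units as the trial-amplitude
#' noise, so `amp_scale = 3 * noise_sd` gives a 3x signal-to-noise ratio for
#' the windowed response amplitudes. Identity tuning is graded by default:
#' each identity neuron responds to every odor at a distinct level (a random
#' permutation of equally spaced levels spanning `[-1.25, 1.25] * amp_scale`,
#' lightly jittered), so any two odors evoke separably different responses
#' -- the defining property of an identity code. Setting `identity_breadth`
#' to an integer switches to sparse tuning (that many preferred odors at
#' full amplitude), which models narrowly tuned units but is not guaranteed
#' to discriminate every odor pair.
#'
#' @param n_neurons Total neurons.
#' @param class_probs Named vector of class proportions over
#'   `identity`, `valence`, `vigor`, `silent` (normalized internally), or a
#'   named integer vector of exact counts summing to `n_neurons`.
#' @param amp_scale Response amplitude of a fully driven neuron
#'   (fluorescence units, also the scale of the encoding weights).
#' @param noise_sd Trial-to-trial amplitude noise SD (same units).
#' @param identity_breadth `NULL` for graded tuning (default), or the
#'   number of preferred odors per identity neuron for sparse tuning.
#' @param frac_inhibited Probability a neuron responds with negative sign.
#' @param baseline_range Range of per-neuron baseline fluorescence (a.u.).
#' @param drift_slope_sd SD of the linear baseline drift slope (a.u./s).
#' @param drift_sin_amp Amplitude of the slow sinusoidal baseline drift.
#' @param fluo_noise_sd Frame-level fluorescence noise SD (a.u.).
#' @param kernel_tau Calcium decay time constant (s).
#' @param seed Integer seed.
#' @return A tibble of class `ground_truth`, one row per neuron, with a
#'   list-column `w_identity` (length-6 weight vectors over the odor panel)
#'   and scalar columns `w_valence`, `w_lick`, `sign`, `baseline_level`,
#'   `drift_slope`, `drift_sin_amp`, `drift_sin_period`, `noise_sd`,
#'   `fluo_noise_sd`, `kernel_tau`, `encoder_class`.
#' @export
#' @examples
#' truth <- make_ground_truth(20, c(valence = 1), seed = 1)
#' table(truth$encoder_class)
make_ground_truth <- function(n_neurons,
                              class_probs = c(identity = 0.35, valence = 0.25,
                                              vigor = 0.15, silent = 0.25),
                              amp_scale = 0.3,
                              noise_sd = 0.1,
                              identity_breadth = NULL,
                              frac_inhibited = 0.25,
                              baseline_range = c(40, 80),
                              drift_slope_sd = 0.002,
                              drift_sin_amp = 0.5,
                              fluo_noise_sd = 0.3,
                              kernel_tau = 1.5,
                              seed = NULL) {
  stopifnot(n_neurons >= 1, amp_scale >= 0, noise_sd >= 0, kernel_tau > 0)
  if (!is.null(seed)) set.seed(seed)
  classes <- c("identity", "valence", "vigor", "silent")
  cp <- class_probs[intersect(names(class_probs), classes)]
  if (length(cp) == 0) abort("`class_probs` must name at least one encoder class")

  if (all(cp == round(cp)) && sum(cp) == n_neurons && any(cp > 1 | sum(cp) == n_neurons)) {
    cls <- sample(rep(names(cp), times = cp))
  } else {
    cls <- sample(names(cp), n_neurons, replace = TRUE, prob = cp / sum(cp))
  }

  sign_vec <- ifelse(runif(n_neurons) < frac_inhibited, -1, 1)
  w_identity <- vector("list", n_neurons)
  w_valence <- numeric(n_neurons)
  w_lick <- numeric(n_neurons)
  for (i in seq_len(n_neurons)) {
    w <- numeric(6)
    if (cls[i] == "identity") {
      if (is.null(identity_breadth)) {
        levels <- seq(-1.25, 1.25, length.out = 6)
        w <- amp_scale * (sample(levels) + rnorm(6, 0, 0.05))
      } else {
        pref <- sample(6, identity_breadth)
        w[pref] <- amp_scale * runif(identity_breadth, 0.7, 1.3)
      }
    } else if (cls[i] == "valence") {
      w_valence[i] <- amp_scale * runif(1, 0.7, 1.3)
    } else if (cls[i] == "vigor") {
      w_lick[i] <- amp_scale * runif(1, 0.7, 1.3)
    }
    w_identity[[i]] <- w
  }

  out <- tibble(
    neuron = seq_len(n_neurons),
    encoder_class = cls,
    sign = sign_vec,
    w_identity = w_identity,
    w_valence = w_valence,
    w_lick = w_lick,
    baseline_level = runif(n_neurons, baseline_range[1], baseline_range[2]),
    drift_slope = rnorm(n_neurons, 0, drift_slope_sd),
    drift_sin_amp = rep(drift_sin_amp, n_neurons),
    drift_sin_period = runif(n_neurons, 400, 800),
    noise_sd = rep(noise_sd, n_neurons),
    fluo_noise_sd = rep(fluo_noise_sd, n_neurons),
    kernel_tau = rep(kernel_tau, n_neurons)
  )
  structure(out, class = c("ground_truth", class(out)))
}
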