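# Fixture builders shared across the test files. Everything is generated
# in code at test time; no stored data.

# A small trial table (exp1 day 3 unless stated otherwise).
small_trials <- function(n_blocks = 5, seed = 1, paradigm = "exp1", day = 3) {
  build_trial_table(make_odor_scheme(paradigm, day = day),
                    n_blocks = n_blocks, seed = seed)
}

# Ground truth in which every neuron is the same pure encoder class.
pure_truth <- function(n_neurons, class, amp_scale = 0.3, noise_sd = 0.1,
                       seed = 1, frac_inhibited = 0, ...) {
  probs <- setNames(1, class)
  make_ground_truth(n_neurons, class_probs = probs, amp_scale = amp_scale,
                    noise_sd = noise_sd, frac_inhibited = frac_inhibited,
                    seed = seed, ...)
}

# trials x neurons feature matrix (window amplitudes) for a pure-encoder
# population, plus its trial labels. SNR = amp_scale / noise_sd.
pure_population_features <- function(class, n_neurons = 15, n_blocks = 10,
                                     amp_scale = 0.3, noise_sd = 0.1,
                                     seed = 1, paradigm = "exp1", day = 3,
                                     behavior = NULL, ...) {
  trials <- small_trials(n_blocks, seed = seed, paradigm = paradigm, day = day)
  truth <- pure_truth(n_neurons, class, amp_scale, noise_sd, seed = seed + 1, ...)
  if (class == "vigor" && is.null(behavior)) {
    behavior <- simulate_behavior(trials, attr(trials, "scheme"),
                                  learning_rate = 0.3, learning_midpoint = 10,
                                  seed = seed + 2)
  }
  amp <- simulate_population(truth, trials, behavior, seed = seed + 3)
  list(features = t(amp), labels = trials$odor, trials = trials,
       truth = truth, amplitudes = amp,
       lick_regressor = attr(amp, "lick_regressor"))
}

# Deterministic dff tensor built directly from a per-neuron x odor response
# template: response `resp[n, o]` is added on odor frames [0, 2) of every
# trial of odor o (constant within the window), zero elsewhere, plus
# optional iid noise. Gives exact control for closed-form checks.
template_tensor <- function(resp, n_blocks = 5, pre_s = 2, post_s = 8,
                            noise_sd = 0, seed = 1,
                            window = c(0, 2), paradigm = "exp1", day = 3) {
  trials <- small_trials(n_blocks, seed = seed, paradigm = paradigm, day = day)
  scheme <- attr(trials, "scheme")
  rate <- 5
  n_fr <- (pre_s + post_s) * rate
  ta <- (seq_len(n_fr) - pre_s * rate - 1) / rate
  n <- nrow(resp)
  tensor <- array(0, c(n, nrow(trials), n_fr))
  if (noise_sd > 0) {
    set.seed(seed + 99)
    tensor <- tensor + array(rnorm(length(tensor), 0, noise_sd), dim(tensor))
  }
  on_f <- which(ta >= window[1] - 1e-9 & ta < window[2] - 1e-9)
  for (i in seq_len(nrow(trials))) {
    o <- match(trials$odor[i], scheme$odor)
    tensor[, i, on_f] <- tensor[, i, on_f] + resp[, o]
  }
  structure(tensor, class = "dff_tensor", time_axis = ta, trials = trials,
            frame_rate = rate)
}

# Brute-force Mann-Whitney oracle: counts wins and half-ties over all
# cross-pairs, folded. Independent of the package's rank-based routine.
brute_force_auroc <- function(values, positive) {
  x1 <- values[positive]
  x0 <- values[!positive]
  wins <- 0
  for (a in x1) for (b in x0) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  a <- wins / (length(x1) * length(x0))
  max(a, 1 - a)
}

# Adjusted Rand index between two labelings (closed form from the
# contingency table).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
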