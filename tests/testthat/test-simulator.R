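test_that("identical configuration and seed reproduce a bit-identical session", {
  a <- simulate_session(8, n_blocks = 2, seed = 11)
  b <- simulate_session(8, n_blocks = 2, seed = 11)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_identical(a$trials, b$trials)
  expect_identical(a$behavior$lick_times, b$behavior$lick_times)
  expect_identical(a$truth, b$truth)
  c <- simulate_session(8, n_blocks = 2, seed = 12)
  expect_false(identical(a$fluorescence, c$fluorescence))
})

test_that("the amplitude model reproduces its closed-form cases", {
  trials <- small_trials(5, seed = 2)
  scheme <- attr(trials, "scheme")

  # pure valence, no noise: equal amplitude for both sucrose odors, zero
  # for control and airpuff odors
  truth <- pure_truth(3, "valence", noise_sd = 0, seed = 5)
  amp <- simulate_population(truth, trials)
  s_trials <- trials$odor %in% scheme$odor[scheme$contingency == "S"]
  for (i in 1:3) {
    expect_equal(unique(amp[i, s_trials]), truth$w_valence[i])
    expect_true(all(amp[i, !s_trials] == 0))
  }

  # pure vigor: amplitudes track anticipatory lick counts
  behavior <- simulate_behavior(trials, scheme, learning_rate = 0.3,
                                learning_midpoint = 10, seed = 6)
  truth_v <- pure_truth(5, "vigor", amp_scale = 1, noise_sd = 0.1, seed = 7)
  amp_v <- simulate_population(truth_v, trials, behavior, seed = 8)
  licks <- anticipatory_licks(behavior, trials)$licks
  cors <- apply(amp_v, 1, stats::cor, y = licks)
  expect_true(all(cors > 0.7))

  # dimension mismatch errors
  bad <- truth
  bad$w_identity[[1]] <- numeric(3)
  expect_error(simulate_population(bad, trials), "length 6")
})

test_that("pure encoder classes span the expected amplitude-matrix ranks at zero noise", {
  trials <- small_trials(5, seed = 3)
  scheme <- attr(trials, "scheme")
  behavior <- simulate_behavior(trials, scheme, learning_rate = 0.3,
                                learning_midpoint = 10, seed = 4)
  rk <- function(m) qr(m)$rank
  amp_id <- simulate_population(pure_truth(20, "identity", noise_sd = 0, seed = 1),
                                trials)
  expect_lte(rk(amp_id), 6)
  amp_val <- simulate_population(pure_truth(20, "valence", noise_sd = 0, seed = 2),
                                 trials)
  expect_lte(rk(amp_val), 1)
  amp_vig <- simulate_population(pure_truth(20, "vigor", noise_sd = 0, seed = 3),
                                 trials, behavior)
  expect_lte(rk(amp_vig), 1)
})

test_that("calcium rendering follows the exponential-decay kernel closed form", {
  trials <- small_trials(1, seed = 4)
  n_tr <- nrow(trials)

  # zero amplitude, zero noise, zero drift: fluorescence is the baseline
  truth0 <- pure_truth(1, "silent", seed = 1)
  truth0$drift_slope <- 0
  truth0$drift_sin_amp <- 0
  truth0$fluo_noise_sd <- 0
  fl <- render_calcium(matrix(0, 1, n_tr), truth0, trials)
  expect_true(all(fl == truth0$baseline_level))

  # single transient decays by half every tau*ln(2) seconds
  amp <- matrix(0, 1, n_tr)
  amp[1, 1] <- 10
  tau <- truth0$kernel_tau[1]
  fl1 <- render_calcium(amp, truth0, trials)
  ft <- attr(fl1, "frame_times")
  onset <- which(ft >= trials$odor_on[1] - 1e-9)[1]
  expect_equal(fl1[1, onset] - truth0$baseline_level, 10)
  # exact exponential decay on the frame grid
  k <- 0:10
  expect_equal(fl1[1, onset + k] - truth0$baseline_level,
               10 * exp(-k / (tau * 5)))
  # and the half-life sits at tau*ln(2): the nearest frame is within one
  # frame-step of a factor-2 drop
  half_frames <- round(tau * log(2) * 5)
  expect_equal(fl1[1, onset + half_frames] - truth0$baseline_level, 5,
               tolerance = 0.05)

  # clipping keeps fluorescence strictly positive and reports it
  truth_neg <- truth0
  truth_neg$baseline_level <- 0.5
  amp_neg <- matrix(-5, 1, n_tr)
  expect_message(
    fl2 <- render_calcium(amp_neg, truth_neg, trials),
    "clipped"
  )
  expect_true(all(fl2 > 0))
})

test_that("a never-learning animal licks equally across all odors", {
  # pooled across seeds, lick counts during the odor window should not
  # depend on the odor
  counts <- NULL
  for (seed in 1:8) {
    trials <- small_trials(5, seed = seed)
    b <- simulate_behavior(trials, attr(trials, "scheme"),
                           learning_rate = 0, seed = seed + 100)
    al <- anticipatory_licks(b, trials)
    counts <- rbind(counts, cbind(al$licks, match(al$odor, attr(trials, "scheme")$odor)))
  }
  p <- kruskal.test(counts[, 1], counts[, 2])$p.value
  expect_gt(p, 0.01)
})

test_that("a trained animal concentrates anticipatory licking on sucrose odors", {
  trials <- small_trials(10, seed = 5)
  scheme <- attr(trials, "scheme")
  b <- simulate_behavior(trials, scheme, learning_rate = 10,
                         learning_midpoint = 0, seed = 9)
  lm1 <- lick_metrics(b, trials)
  expect_gt(lm1$s_fraction, 0.8)
})

test_that("spout removal suppresses licking until the spout returns", {
  trials <- small_trials(10, seed = 6, paradigm = "exp2")
  scheme <- attr(trials, "scheme")
  b <- simulate_behavior(trials, scheme, learning_rate = 10,
                         learning_midpoint = 0, seed = 10)
  n_odors <- scheme$odor[scheme$spout == "N"]
  n_tr <- trials[trials$odor %in% n_odors, ]
  # per-frame lick probability during the spout-absent odor window
  p_lick <- mean(vapply(seq_len(nrow(n_tr)), function(i) {
    idx <- which(b$frame_times >= n_tr$odor_on[i] &
                 b$frame_times < n_tr$odor_off[i] + 1.0)
    mean(b$lick_state[idx])
  }, numeric(1)))
  expect_lt(p_lick, 0.05)
})

test_that("face features trace the lick state with the configured noise", {
  trials <- small_trials(5, seed = 7)
  b <- simulate_behavior(trials, attr(trials, "scheme"), learning_rate = 10,
                         learning_midpoint = 0, feature_noise_sd = 0.05,
                         seed = 11)
  on <- b$lick_state == 1
  expect_gt(mean(b$face_features[on, 1]) - mean(b$face_features[!on, 1]), 0.5)
})

test_that("session containers round-trip through the plain-text format", {
  s <- simulate_session(5, n_blocks = 2, seed = 21)
  dir <- withr::local_tempdir()
  write_session(s, file.path(dir, "sess"))
  expect_error(write_session(s, file.path(dir, "sess")), "already exists")
  r <- read_session(file.path(dir, "sess"))
  expect_equal(unclass(r$fluorescence)[, ], unclass(s$fluorescence)[, ],
               tolerance = 1e-12)
  expect_equal(r$trials$odor, s$trials$odor)
  expect_equal(r$trials$us_time, s$trials$us_time)
  expect_equal(r$behavior$lick_times, s$behavior$lick_times)
  expect_equal(r$truth$w_valence, s$truth$w_valence)
  expect_equal(r$truth$w_identity, s$truth$w_identity)
})
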