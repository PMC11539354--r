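# Minimal hand-built behavior trace: lick timestamps on a 5 Hz clock.
fake_behavior <- function(lick_times, duration) {
  ft <- seq(0, duration, by = 0.2)
  counts <- vapply(ft, function(t0) sum(lick_times >= t0 & lick_times < t0 + 0.2),
                   numeric(1))
  structure(list(
    lick_times = sort(lick_times), frame_times = ft, lick_count = counts,
    lick_state = as.numeric(counts > 0),
    locomotion = rep(1, length(ft)), eye_area = rep(1, length(ft)),
    face_features = matrix(0, length(ft), 3), spout_in = rep(TRUE, length(ft)),
    frame_rate = 5
  ), class = "behavior_trace")
}

test_that("lick metrics compute rates, trends, and the sucrose-cue fraction", {
  trials <- small_trials(2, seed = 1)
  scheme <- attr(trials, "scheme")
  s_odors <- scheme$odor[scheme$contingency == "S"]

  # licks only during sucrose odors: fraction exactly 1
  s_rows <- which(trials$odor %in% s_odors)
  licks <- unlist(lapply(s_rows, function(i) trials$odor_on[i] + c(0.5, 1.0, 1.5)))
  b <- fake_behavior(licks, max(trials$us_time) + 5)
  m <- lick_metrics(b, trials)
  expect_equal(m$s_fraction, 1)
  expect_equal(sum(m$per_trial$licks), 3 * length(s_rows))
  expect_equal(m$per_odor$rate[m$per_odor$odor == s_odors[1]], 1.5) # 3 licks / 2 s

  # uniform licking across odors: fraction = 2/6
  licks_u <- unlist(lapply(seq_len(nrow(trials)),
                           function(i) trials$odor_on[i] + c(0.5, 1.0)))
  mu <- lick_metrics(fake_behavior(licks_u, max(trials$us_time) + 5), trials)
  expect_equal(mu$s_fraction, 1 / 3)

  # no licks at all: undefined fraction with a warning
  expect_warning(m0 <- lick_metrics(fake_behavior(numeric(0), 300), trials),
                 "undefined")
  expect_true(is.na(m0$s_fraction))

  # moving-average trend is a trailing mean over the stated window
  pt <- mu$per_trial[mu$per_trial$odor == trials$odor[1], ]
  expect_equal(pt$trend[1], pt$licks[1])
})

test_that("the exp2 analysis window spans the last 0.5 s of odor and first 0.5 s of delay", {
  trials <- small_trials(3, seed = 2, paradigm = "exp2")
  i <- 1
  lick_in <- trials$odor_on[i] + c(1.6, 2.4) # inside [1.5, 2.5)
  lick_out <- trials$odor_on[i] + c(0.5, 2.6) # outside
  b <- fake_behavior(c(lick_in, lick_out), max(trials$us_time) + 5)
  al <- anticipatory_licks(b, trials, window = c(1.5, 2.5))
  expect_equal(al$licks[i], 2)
})

test_that("the face-feature classifier separates licking frames and respects the no-signal floor", {
  set.seed(3)
  n <- 1200
  y <- rbinom(n, 1, 0.3)
  sep <- cbind(y * 0.9, y * 0.7, y * 2) +
    matrix(rnorm(n * 3, 0, 0.3 / 3), n) # 3x class separation on channel 1
  fit <- face_lick_classifier(sep, y, seed = 4)
  expect_gte(fit$cv_accuracy, 0.95)
  expect_length(fit$probability, n)
  # prediction on new frames
  p <- predict(fit, sep[1:10, ])
  expect_true(all(p >= 0 & p <= 1))

  # independent features: accuracy near the majority-class rate
  indep <- matrix(rnorm(n * 3), n)
  accs <- vapply(1:10, function(s) {
    face_lick_classifier(indep, y, seed = s)$cv_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - max(mean(y), 1 - mean(y))), 2 * sd(accs) + 0.02)
  expect_error(face_lick_classifier(indep, rep(1, n)), "single class")
})

test_that("distributed-lag models recover a planted lag and reject white noise", {
  set.seed(5)
  n <- 600
  x <- rnorm(n)
  y <- c(rep(0, 3), x[1:(n - 3)]) + rnorm(n, 0, 0.01) # y_t = x_{t-3}
  fit <- distributed_lag_model(x, y, lags = c(-6, 0))
  co <- fit$coefficients
  expect_equal(co$estimate[co$lag == -3], 1, tolerance = 0.02)
  expect_true(all(abs(co$estimate[co$lag != -3]) < 0.05))
  expect_gt(fit$r2, 0.99)
  expect_equal(tidy(fit), co)
  expect_equal(glance(fit)$r_squared, fit$r2)

  # independent white noise: out-of-sample R^2 stays at the floor
  r2s <- vapply(1:20, function(s) {
    set.seed(100 + s)
    distributed_lag_model(rnorm(400), rnorm(400), lags = c(-5, 0))$r2_cv
  }, numeric(1))
  expect_lte(mean(r2s), 0.02)
  expect_lt(max(r2s), 0.1)

  # collinear degenerate design errors with the condition number named
  xc <- cbind(rnorm(100), 0)
  xc <- cbind(xc[, 1], xc[, 1]) # duplicated channel
  expect_error(distributed_lag_model(xc, rnorm(100), lags = c(0, 0)),
               "condition number")
  expect_error(distributed_lag_model(rnorm(10), rnorm(10), lags = c(-12, 0)),
               "shorter")
})

test_that("lick-coupled neurons predict bout onsets above a shuffled control", {
  set.seed(6)
  wins <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 500
    bout_frames <- sort(sample(20:(n - 10), 15))
    y <- numeric(n); y[bout_frames] <- 1
    # neuron rises two frames before each bout onset
    x <- numeric(n)
    for (b0 in bout_frames) x[(b0 - 2):b0] <- x[(b0 - 2):b0] + 1
    x <- x + rnorm(n, 0, 0.3)
    fit <- distributed_lag_model(x, y, lags = c(-4, 4))
    fit_sh <- distributed_lag_model(x, sample(y), lags = c(-4, 4))
    fit$r2_cv > fit_sh$r2_cv
  }, logical(1))
  expect_gt(mean(wins), 0.5)
  p_binom <- stats::binom.test(sum(wins), length(wins),
                               alternative = "greater")$p.value
  expect_lt(p_binom, 0.05)
})

test_that("bout onsets respect the quiet gap and minimum lick count", {
  licks <- c(1.0, 1.1, 1.2, 1.3,      # bout at 1.0 (after >= 1 s quiet)
             5.0,                      # isolated lick: not a bout
             9.0, 9.2, 9.4, 9.5)       # bout at 9.0
  onsets <- lick_bout_onsets(licks)
  expect_equal(onsets, c(1.0, 9.0))
  # every onset is preceded by a lick-free quiet gap
  for (t0 in onsets) {
    expect_equal(sum(licks >= t0 - 1 & licks < t0), 0)
  }
  expect_equal(lick_bout_onsets(numeric(0)), numeric(0))
})

test_that("delta-R^2 decoupling separates contingency-coded from lick-coded neurons", {
  set.seed(7)
  n_tr <- 90
  ps <- sample(c(0, 0.5, 1), n_tr, replace = TRUE)
  licks <- rpois(n_tr, 3) # independent of contingency
  val_ok <- 0; lick_ok <- 0; reps <- 15
  for (r in 1:reps) {
    y_val <- 0.3 * ps + rnorm(n_tr, 0, 0.05)
    y_lick <- 0.1 * licks + rnorm(n_tr, 0, 0.05)
    d <- delta_r2_decoupling(rbind(y_val, y_lick), ps, licks)
    expect_true(all(d$delta_r2_valence >= -1e-12))
    expect_true(all(d$delta_r2_licking >= -1e-12))
    if (d$delta_r2_valence[1] > 0.5 && d$delta_r2_licking[1] < 0.05) val_ok <- val_ok + 1
    if (d$delta_r2_licking[2] > 0.5 && d$delta_r2_valence[2] < 0.05) lick_ok <- lick_ok + 1
  }
  expect_gte(val_ok / reps, 0.9)
  expect_gte(lick_ok / reps, 0.9)

  expect_warning(delta_r2_decoupling(rnorm(20), rep(1, 20), rpois(20, 2)),
                 "constant contingency")
  expect_error(delta_r2_decoupling(rnorm(5), rep(0:1, 3)[1:5], rpois(5, 2)),
               "10 trials")
})

test_that("accuracy-behavior models recover planted effects and respect nesting", {
  set.seed(8)
  n_pairs <- 15
  dps <- runif(n_pairs)
  dlick <- runif(n_pairs, 0, 7) # independent of dps
  acc <- 0.5 + 0.3 * dps + rnorm(n_pairs, 0, 0.01)
  fits <- accuracy_behavior_models(acc, dlick, dps)
  g <- glance(fits)
  # P(S)-only model recovers the slope; lick-only model explains little
  td <- tidy(fits)
  slope <- td$estimate[td$model == "ps_only" & td$term == "delta_ps"]
  se <- td$std_error[td$model == "ps_only" & td$term == "delta_ps"]
  expect_lt(abs(slope - 0.3), 1.96 * se)
  expect_lt(g$r_squared[g$model == "lick_only"], 0.3)
  # nesting: combined R^2 >= each single-variable R^2
  expect_gte(g$r_squared[g$model == "combined"],
             max(g$r_squared[g$model != "combined"]) - 1e-12)
  # the lick regressor is range-normalized before fitting
  expect_equal(range(fits$data$delta_lick), c(0, 1))
  expect_error(accuracy_behavior_models(acc, rep(1, n_pairs), dps),
               "zero-variance")
})

test_that("disjoint valence- and lick-coding subpopulations dissociate in auROC space", {
  # exp2-style session: contingency encoders decode N_hi vs N_X but not
  # L_hi vs N_hi; the correlation structure across neurons mirrors this
  cors_decoupled <- c(); cors_coupled <- c()
  for (seed in 1:8) {
    trials <- small_trials(15, seed = seed, paradigm = "exp2")
    scheme <- attr(trials, "scheme")
    behavior <- simulate_behavior(trials, scheme, learning_rate = 10,
                                  learning_midpoint = 0, seed = seed + 20)
    truth <- rbind(
      pure_truth(10, "valence", seed = seed + 40),
      pure_truth(10, "vigor", seed = seed + 60),
      pure_truth(10, "silent", seed = seed + 100)
    )
    truth$neuron <- seq_len(nrow(truth))
    class(truth) <- c("ground_truth", "tbl_df", "tbl", "data.frame")
    amp <- simulate_population(truth, trials, behavior,
                               seed = seed + 80)
    role <- setNames(scheme$odor, scheme$role)
    a_of <- function(pair) {
      idx <- trials$odor %in% pair
      vapply(seq_len(nrow(truth)), function(i) {
        fit_pairwise_auroc(amp[i, idx], trials$odor[idx])$auroc
      }, numeric(1))
    }
    a_value <- a_of(c(role[["N_hi"]], role[["N_X"]]))   # contingency axis
    a_vigor <- a_of(c(role[["L_hi"]], role[["N_hi"]]))  # licking axis
    a_value2 <- a_of(c(role[["L_hi"]], role[["L_X"]]))  # second contingency axis
    cors_decoupled <- c(cors_decoupled, cor(a_value, a_vigor))
    cors_coupled <- c(cors_coupled, cor(a_value, a_value2))
  }
  # both-contingency axes co-vary across neurons ...
  expect_lt(stats::t.test(cors_coupled, alternative = "greater")$p.value, 0.05)
  # ... while the contingency and licking axes do not
  expect_gt(stats::t.test(cors_decoupled, alternative = "greater")$p.value, 0.05)
  expect_lt(mean(cors_decoupled), mean(cors_coupled))
})
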