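test_that("stratified 5-fold CV partitions 60 trials into folds of 12", {
  labs <- rep(c("a", "b"), each = 30)
  rec <- cv_pairwise_accuracy(matrix(rnorm(60 * 4), 60), labs, seed = 1)
  folds <- rec$fold_accuracies[[1]]
  expect_length(folds, 5)
  expect_equal(rec$cv_accuracy, mean(folds))
  # fold sizes recoverable from the internal assignment: re-derive
  set.seed(1)
  f <- odorvalence:::stratified_folds(labs, 5)
  expect_true(all(table(f) == 12))
  expect_true(all(table(f, labs) == 6))
})

test_that("decoders stay at chance without label-feature association", {
  set.seed(2)
  accs <- vapply(1:25, function(i) {
    X <- matrix(rnorm(40 * 10), 40)
    cv_pairwise_accuracy(X, rep(c("a", "b"), each = 20))$cv_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 2 * sd(accs) / sqrt(length(accs)) + 0.03)
})

test_that("separable populations decode at >= 0.95 with both learners", {
  for (seed in 1:5) {
    pop <- pure_population_features("valence", n_neurons = 15, n_blocks = 30,
                                    amp_scale = 0.3, noise_sd = 0.1,
                                    seed = seed * 13)
    trials <- pop$trials
    scheme <- attr(trials, "scheme")
    role <- setNames(scheme$odor, scheme$role)
    idx <- trials$odor %in% c(role[["S_K"]], role[["X_K"]])
    X <- pop$features[idx, ]
    labs <- trials$odor[idx]
    acc_log <- cv_pairwise_accuracy(X, labs, "logistic", seed = seed)$cv_accuracy
    acc_svm <- cv_pairwise_accuracy(X, labs, "svm_rbf", seed = seed)$cv_accuracy
    expect_gte(acc_log, 0.95)
    expect_gte(acc_svm, 0.9)
  }
})

test_that("permutation p-values are small for decodable pairs and fold assignment is deterministic", {
  pop <- pure_population_features("valence", n_neurons = 10, n_blocks = 20,
                                  seed = 3)
  trials <- pop$trials
  scheme <- attr(trials, "scheme")
  role <- setNames(scheme$odor, scheme$role)
  idx <- trials$odor %in% c(role[["S_K"]], role[["P_K"]])
  r1 <- cv_pairwise_accuracy(pop$features[idx, ], trials$odor[idx],
                             n_shuffles = 99, seed = 7)
  r2 <- cv_pairwise_accuracy(pop$features[idx, ], trials$odor[idx],
                             n_shuffles = 99, seed = 7)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_identical(r1$null_p, r2$null_p)
  expect_equal(r1$null_p, 1 / 100)
})

test_that("time-resolved accuracy is at chance before odor onset and rises after", {
  # population responding from onset on; pre-odor frames carry no signal
  resp <- rbind(c(0.5, 0, 0, 0, 0, 0), c(0, 0.4, 0, 0, 0, 0),
                c(0.3, -0.3, 0, 0, 0, 0), c(-0.2, 0.4, 0, 0, 0, 0),
                c(0.4, 0.2, 0, 0, 0, 0))
  tensor <- template_tensor(resp, n_blocks = 8, noise_sd = 0.1, seed = 4)
  ta <- attr(tensor, "time_axis")
  out <- time_resolved_accuracy(tensor, c("hexanone", "heptanone"), seed = 5)
  pre <- out$accuracy[ta < 0]
  post <- out$accuracy[ta >= 0.2 & ta < 2]
  expect_lt(abs(mean(pre) - 0.5), 0.12)
  expect_gt(mean(post), 0.9)
  expect_equal(attr(out, "window_summary"),
               mean(out$accuracy[ta >= 1 - 1e-9 & ta < 2 - 1e-9]))
})

test_that("valence populations generalize across odor pairs; identity populations do not", {
  gen_acc <- function(class, seed) {
    pop <- pure_population_features(class, n_neurons = 15, n_blocks = 10,
                                    amp_scale = 0.3, noise_sd = 0.1,
                                    seed = seed)
    trials <- pop$trials
    scheme <- attr(trials, "scheme")
    role <- setNames(scheme$odor, scheme$role)
    train_pair <- c(role[["S_K"]], role[["P_K"]])
    test_pair <- c(role[["S_T"]], role[["X_T"]])
    tr_idx <- trials$odor %in% train_pair
    te_idx <- trials$odor %in% test_pair
    sc <- odorvalence:::train_scaler(pop$features[tr_idx, ])
    m <- odorvalence:::fit_binary(sc(pop$features[tr_idx, ]),
                                  trials$odor[tr_idx] == train_pair[1],
                                  "logistic")
    mean(odorvalence:::predict_binary(m, sc(pop$features[te_idx, ])) ==
           (trials$odor[te_idx] == test_pair[1]))
  }
  val <- vapply(1:15, function(s) gen_acc("valence", 1000 + s), numeric(1))
  id <- vapply(1:15, function(s) gen_acc("identity", 2000 + s), numeric(1))
  expect_gte(mean(val), 0.9)
  expect_lt(abs(mean(id) - 0.5), 2 * sd(id))
})

test_that("the 15 x 15 generalization matrix has consistent structure on a valence population", {
  resp <- matrix(0, 12, 6)
  tensor <- template_tensor(resp, n_blocks = 8, noise_sd = 0.1, seed = 6)
  trials <- attr(tensor, "trials")
  scheme <- attr(trials, "scheme")
  truth <- pure_truth(12, "valence", seed = 61)
  amp <- simulate_population(truth, trials, seed = 62)
  ta <- attr(tensor, "time_axis")
  on_f <- which(ta >= 0 & ta < 2 - 1e-9)
  for (i in seq_len(nrow(trials))) {
    tensor[, i, on_f] <- tensor[, i, on_f] + amp[, i]
  }
  gen <- generalization_matrix(tensor, seed = 63)
  expect_equal(nrow(gen), 225)
  expect_setequal(unique(c(gen$train_pair, gen$test_pair)),
                  unique(gen$train_pair))
  # intervalence train/test cells generalize well for a valence code
  iv <- grepl("^S_._vs_|^S_. vs ", gen$train_pair) &
    !grepl("vs S_.", gen$train_pair)
  inter_train <- grepl("^S_", gen$train_pair) & !grepl("vs S_", gen$train_pair)
  inter_test <- grepl("^S_", gen$test_pair) & !grepl("vs S_", gen$test_pair)
  cells <- gen$accuracy[inter_train & inter_test & !gen$diagonal]
  expect_gt(mean(cells), 0.85)
  # diagonal flagged
  expect_equal(sum(gen$diagonal), 15)
})

test_that("population confusion matrices are row-stochastic and mirror the encoding", {
  pop <- pure_population_features("valence", n_neurons = 12, n_blocks = 6,
                                  seed = 8)
  cm <- population_confusion(pop$features, pop$labels, seed = 9)
  expect_equal(unname(rowSums(cm)), rep(1, 6), tolerance = 1e-12)
  trials <- pop$trials
  scheme <- attr(trials, "scheme")
  role <- setNames(scheme$odor, scheme$role)
  expect_gt(cm[role[["S_K"]], role[["S_T"]]], cm[role[["S_K"]], role[["X_K"]]])

  pop_id <- pure_population_features("identity", n_neurons = 12, n_blocks = 6,
                                     seed = 10)
  cm_id <- population_confusion(pop_id$features, pop_id$labels, seed = 11)
  expect_gt(mean(diag(cm_id)), 0.5)
})

test_that("PCA-restricted decoding is rotation-invariant at full rank and rank-aware below", {
  # k = n_sub reproduces full-feature accuracy (PCA is a rotation)
  pop <- pure_population_features("identity", n_neurons = 15, n_blocks = 30,
                                  seed = 12)
  trials <- pop$trials
  scheme <- attr(trials, "scheme")
  role <- setNames(scheme$odor, scheme$role)
  idx <- trials$odor %in% c(role[["S_K"]], role[["S_T"]])
  X <- pop$features[idx, ]
  labs <- trials$odor[idx]
  curve <- pca_restricted_accuracy(X, labs, n_sub = 15, k_pcs = 15,
                                   n_resamples = 3, seed = 13)
  full <- mean(vapply(1:5, function(s) {
    cv_pairwise_accuracy(X, labs, seed = s)$cv_accuracy
  }, numeric(1)))
  expect_lt(abs(curve$accuracy[curve$k == 15] - full), 0.1)

  # rank-1 valence population: first PC suffices
  popv <- pure_population_features("valence", n_neurons = 15, n_blocks = 30,
                                   seed = 14)
  tv <- popv$trials
  idxv <- tv$odor %in% c(role[["S_K"]], role[["P_K"]])
  cv_curve <- pca_restricted_accuracy(popv$features[idxv, ], tv$odor[idxv],
                                      n_sub = 15, k_pcs = c(1, 15),
                                      n_resamples = 3, seed = 15)
  expect_lt(abs(cv_curve$accuracy[cv_curve$k == 1] -
                cv_curve$accuracy[cv_curve$k == 15]), 0.05)
  expect_error(pca_restricted_accuracy(X, labs, n_sub = 15, k_pcs = 16),
               "k_pcs")
})

test_that("a weak distributed signal under a dominant shared mode needs many PCs", {
  # per-neuron pair signal well below noise, population signal strong, and
  # a common-mode fluctuation that owns the first PC: one component decodes
  # at chance, the full rank recovers the distributed signal
  set.seed(16)
  n_tr <- 60; n_neu <- 15
  labs <- rep(c("a", "b"), each = n_tr / 2)
  delta <- rnorm(n_neu, 0, 0.05)
  common <- rnorm(n_tr, 0, 0.4)
  X <- outer(as.numeric(labs == "b"), delta) +
    outer(common, rep(1, n_neu)) +
    matrix(rnorm(n_tr * n_neu, 0, 0.05), n_tr)
  curve <- pca_restricted_accuracy(X, labs, n_sub = 15, k_pcs = c(1, 15),
                                   n_resamples = 5, seed = 17)
  expect_lt(abs(curve$accuracy[curve$k == 1] - 0.5), 0.15)
  expect_gt(curve$accuracy[curve$k == 15] - curve$accuracy[curve$k == 1], 0.15)
})

test_that("errors name the violated precondition", {
  expect_error(cv_pairwise_accuracy(matrix(rnorm(30), 10), rep("a", 10)),
               "two classes")
  expect_error(cv_pairwise_accuracy(matrix(rnorm(30), 10),
                                    c(rep("a", 8), "b", "b")),
               "fewer than")
  expect_error(odorvalence:::fit_binary(matrix(1, 2, 2), c(TRUE, FALSE), "nope"),
               "unknown learner")
})
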