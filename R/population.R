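# Population decoding: cross-validated pairwise classifiers, permutation
# nulls, time-resolved decoding, cross-pair generalization, multinomial
# confusion, and PCA-restricted decoding.

# Binary learners share one interface so logistic and RBF-SVM results are
# interchangeable. Logistic fits are unregularized; rank-deficient designs
# (more neurons than trials) are handled by zeroing aliased coefficients.
fit_binary <- function(X, y, learner) {
  if (learner == "logistic") {
    fit <- suppressWarnings(glm.fit(cbind(1, X), y, family = binomial()))
    co <- fit$coefficients
    co[!is.finite(co)] <- 0
    list(learner = "logistic", coef = co)
  } else if (learner == "svm_rbf") {
    gam <- 1 / (ncol(X) * max(mean(apply(X, 2, var)), 1e-12))
    list(learner = "svm_rbf",
         model = e1071::svm(X, factor(y), kernel = "radial", cost = 1,
                            gamma = gam, scale = FALSE))
  } else {
    abort(sprintf("unknown learner '%s'", learner))
  }
}

predict_binary <- function(model, X) {
  if (model$learner == "logistic") {
    as.vector(cbind(1, X) %*% model$coef) > 0
  } else {
    as.logical(as.character(predict(model$model, X)))
  }
}

# z-scoring with training-set statistics, applied to any matrix
train_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  function(M) sweep(sweep(M, 2, mu), 2, sdv, "/")
}

#' Cross-validated pairwise population decoding accuracy
#'
#' Trains a binary classifier (logistic or RBF-kernel SVM) on a
#' `trials x neurons` feature matrix under stratified k-fold
#' cross-validation. Features are Z-scored with training-fold statistics
#' inside each fold. An optional permutation null refits the full CV on
#' label shuffles that preserve class counts, giving
#' `p = (1 + #(shuffled >= observed)) / (n_shuffles + 1)`.
#'
#' @param features `trials x neurons` matrix.
#' @param labels Two-class label per trial.
#' @param learner `"logistic"` or `"svm_rbf"` (cost 1, gamma
#'   `1/(n_features * mean feature variance)`).
#' @param folds Stratified CV folds.
#' @param n_shuffles Label permutations for the null (0 skips it).
#' @param seed Integer seed (fold assignment and shuffles).
#' @return A one-row tibble of class `decoder_record`: `learner`,
#'   `cv_accuracy`, `fold_accuracies` (list-column), `null_p`,
#'   `n_shuffles`, `n_trials`.
#' @export
cv_pairwise_accuracy <- function(features, labels, learner = c("logistic", "svm_rbf"),
                                 folds = 5, n_shuffles = 0, seed = NULL) {
  learner <- match.arg(learner)
  if (!is.null(seed)) set.seed(seed)
  lev <- unique(labels)
  if (length(lev) != 2) abort("`labels` must have exactly two classes")
  y <- labels == lev[2]

  run_cv <- function(yy) {
    fold <- stratified_folds(yy, folds)
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      sc <- train_scaler(features[tr, , drop = FALSE])
      m <- fit_binary(sc(features[tr, , drop = FALSE]), yy[tr], learner)
      acc[f] <- mean(predict_binary(m, sc(features[!tr, , drop = FALSE])) == yy[!tr])
    }
    acc
  }

  acc <- run_cv(y)
  null_p <- NA_real_
  if (n_shuffles > 0) {
    obs <- mean(acc)
    null <- vapply(seq_len(n_shuffles),
                   function(s) mean(run_cv(sample(y))), numeric(1))
    null_p <- (1 + sum(null >= obs - 1e-12)) / (n_shuffles + 1)
  }
  out <- tibble(learner = learner, cv_accuracy = mean(acc),
                fold_accuracies = list(acc), null_p = null_p,
                n_shuffles = n_shuffles, n_trials = length(y))
  class(out) <- c("decoder_record", class(out))
  out
}

#' Time-resolved pairwise decoding accuracy
#'
#' Runs [cv_pairwise_accuracy()] at every frame of the trial tensor, using
#' the single-frame dF/F of each neuron as features. The window summary is
#' the mean accuracy over the last second of the odor period.
#'
#' @param tensor A [align_trials()] tensor.
#' @param pair Character vector of two odor labels.
#' @param learner,folds,seed As in [cv_pairwise_accuracy()].
#' @return A tibble of class `time_accuracy`: `time`, `accuracy`; the
#'   attribute `window_summary` holds the mean over `[1, 2)` s.
#' @export
time_resolved_accuracy <- function(tensor, pair, learner = "logistic",
                                   folds = 5, seed = NULL) {
  trials <- attr(tensor, "trials")
  ta <- attr(tensor, "time_axis")
  tr <- which(trials$odor %in% pair)
  labs <- trials$odor[tr]
  n <- dim(tensor)[1]
  acc <- vapply(seq_along(ta), function(k) {
    Xf <- t(matrix(tensor[, tr, k, drop = FALSE], nrow = n))
    cv_pairwise_accuracy(Xf, labs, learner,
                         folds = folds, seed = seed)$cv_accuracy
  }, numeric(1))
  out <- tibble(time = ta, accuracy = acc)
  attr(out, "window_summary") <- mean(acc[frames_in_window(ta, c(1, 2))])
  class(out) <- c("time_accuracy", class(out))
  out
}

# Canonical within-pair class order: the odor with the higher contingency
# value is class 1 in every pair, so "class 1" means the same thing in the
# train and test pairs of a generalization cell. Ties (equal value) fall
# back to contingency-group order then chemical class (ketone first).
pair_order <- function(scheme, o1, o2) {
  v <- odor_value(scheme)
  key <- function(o) {
    g <- if ("contingency" %in% names(scheme)) {
      c(S = 0, X = 1, P = 2)[scheme$contingency[scheme$odor == o]]
    } else {
      0
    }
    ck <- as.numeric(scheme$chem_class[scheme$odor == o] != "ketone")
    c(-v[[o]], g, ck)
  }
  k1 <- key(o1); k2 <- key(o2)
  for (i in seq_along(k1)) {
    if (k1[i] < k2[i]) return(c(o1, o2))
    if (k1[i] > k2[i]) return(c(o2, o1))
  }
  c(o1, o2) # fully tied: keep given order
}

#' Cross-pair generalization matrix of pairwise decoders
#'
#' For every ordered pair of the 15 odor pairs, trains a classifier on the
#' training pair at each odor-period frame and evaluates it on the testing
#' pair's trials at the same frame, reporting the maximum accuracy over
#' odor-period frames. Class labels correspond across pairs through the
#' contingency ordering of [pair_order()], so "class 1" is the
#' higher-contingency odor in both pairs. Diagonal entries are within-pair
#' cross-validated maxima and do not measure generalization.
#'
#' @param tensor A [align_trials()] tensor with all 6 odors.
#' @param learner `"logistic"` or `"svm_rbf"`.
#' @param window Frames scanned, default the 2 s odor period.
#' @param folds CV folds for the diagonal.
#' @param seed Integer seed.
#' @return A tibble of class `generalization_matrix` in long format:
#'   `train_pair`, `test_pair`, `accuracy`, `diagonal`.
#' @export
generalization_matrix <- function(tensor, learner = "logistic",
                                  window = c(0, 2), folds = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials <- attr(tensor, "trials")
  scheme <- attr(trials, "scheme")
  ta <- attr(tensor, "time_axis")
  frames <- frames_in_window(ta, window)
  cmb <- utils::combn(scheme$odor, 2)
  n_pair <- ncol(cmb)
  ordered_pairs <- lapply(seq_len(n_pair), function(k) {
    pair_order(scheme, cmb[1, k], cmb[2, k])
  })
  pair_name <- vapply(ordered_pairs, function(p) {
    role <- setNames(scheme$role, scheme$odor)
    paste(role[p], collapse = " vs ")
  }, character(1))

  pair_trials <- lapply(ordered_pairs, function(p) which(trials$odor %in% p))
  pair_y <- lapply(seq_len(n_pair), function(k) {
    trials$odor[pair_trials[[k]]] == ordered_pairs[[k]][1]
  })

  n_neuron <- dim(tensor)[1]
  frame_feat <- function(tr_idx, f) {
    t(matrix(tensor[, tr_idx, f, drop = FALSE], nrow = n_neuron))
  }

  acc <- array(NA_real_, c(n_pair, n_pair, length(frames)))
  for (i in seq_len(n_pair)) {
    tr_i <- pair_trials[[i]]; y_i <- pair_y[[i]]
    for (fidx in seq_along(frames)) {
      f <- frames[fidx]
      Xtr <- frame_feat(tr_i, f)
      sc <- train_scaler(Xtr)
      m <- fit_binary(sc(Xtr), y_i, learner)
      for (j in seq_len(n_pair)) {
        if (j == i) next
        Xte <- frame_feat(pair_trials[[j]], f)
        acc[i, j, fidx] <- mean(predict_binary(m, sc(Xte)) == pair_y[[j]])
      }
      # diagonal: within-pair CV accuracy at the same frame (folds capped
      # by the class counts in short sessions)
      acc[i, i, fidx] <- cv_pairwise_accuracy(
        Xtr, ifelse(y_i, "pos", "neg"), learner,
        folds = min(folds, sum(y_i), sum(!y_i))
      )$cv_accuracy
    }
  }
  max_acc <- apply(acc, c(1, 2), max)
  out <- tidyr::expand_grid(train_pair = pair_name, test_pair = pair_name) |>
    dplyr::mutate(
      accuracy = as.vector(t(max_acc)),
      diagonal = .data$train_pair == .data$test_pair
    )
  # expand_grid varies the last column fastest -> t() serializes row-major
  class(out) <- c("generalization_matrix", class(out))
  out
}

#' Cross-validated multinomial confusion matrix for a population
#'
#' Trains a multinomial logistic classifier on a `trials x neurons` feature
#' matrix over all six odors with stratified CV and aggregates held-out
#' predictions into a row-stochastic confusion matrix.
#'
#' @param features `trials x neurons` matrix.
#' @param labels Odor label per trial.
#' @param cv_folds Stratified folds.
#' @param seed Integer seed.
#' @return A row-stochastic `6 x 6` matrix (true x predicted).
#' @export
population_confusion <- function(features, labels, cv_folds = 5, seed = NULL) {
  classes <- sort(unique(labels))
  if (any(table(labels) < cv_folds)) abort("every class needs at least `cv_folds` trials")
  fold <- stratified_folds(labels, cv_folds, seed)
  pred <- character(length(labels))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    sc <- train_scaler(features[tr, , drop = FALSE])
    df <- data.frame(sc(features[tr, , drop = FALSE]))
    df$y <- factor(labels[tr], classes)
    fit <- nnet::multinom(y ~ ., df, trace = FALSE, MaxNWts = 5000)
    nd <- data.frame(sc(features[!tr, , drop = FALSE]))
    names(nd) <- setdiff(names(df), "y")
    pred[!tr] <- as.character(predict(fit, nd))
  }
  cm <- table(factor(labels, classes), factor(pred, classes))
  cm <- unclass(cm / rowSums(cm))
  dimnames(cm) <- list(true = classes, predicted = classes)
  cm
}

#' Decoding accuracy restricted to leading principal components
#'
#' Subsamples `n_sub` neurons, computes principal components on the
#' training folds only, projects both folds, and trains a logistic
#' classifier on the first `k` components, for each `k` in `k_pcs`.
#' Accuracies are averaged over stratified folds and neuron resamples. A
#' paper-literal mode computing the PCA on the whole dataset (training and
#' test trials pooled) is available behind `whole_data_pca`.
#'
#' @param features `trials x neurons` matrix (two classes).
#' @param labels Two-class label per trial.
#' @param n_sub Neurons per subsample.
#' @param k_pcs Integer vector of component counts.
#' @param n_resamples Neuron subsamples.
#' @param folds Stratified CV folds.
#' @param whole_data_pca Compute the rotation on all trials (leaks test
#'   variance into the axes; off by default).
#' @param seed Integer seed.
#' @return A tibble `k`, `accuracy` (mean over folds and resamples).
#' @export
pca_restricted_accuracy <- function(features, labels, n_sub = 15,
                                    k_pcs = seq_len(n_sub), n_resamples = 10,
                                    folds = 5, whole_data_pca = FALSE,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ncol(features) < n_sub) abort("population smaller than `n_sub`")
  if (max(k_pcs) > n_sub) abort("`k_pcs` cannot exceed `n_sub`")
  lev <- unique(labels)
  if (length(lev) != 2) abort("`labels` must have exactly two classes")
  y <- labels == lev[2]

  acc <- matrix(0, n_resamples, length(k_pcs))
  for (r in seq_len(n_resamples)) {
    sub <- sample(ncol(features), n_sub)
    X <- features[, sub, drop = FALSE]
    fold <- stratified_folds(y, folds)
    fold_acc <- matrix(0, folds, length(k_pcs))
    for (f in seq_len(folds)) {
      tr <- fold != f
      rot_src <- if (whole_data_pca) X else X[tr, , drop = FALSE]
      pc <- prcomp(rot_src, center = TRUE, scale. = FALSE)
      proj <- function(M) sweep(M, 2, pc$center) %*% pc$rotation
      Ztr <- proj(X[tr, , drop = FALSE])
      Zte <- proj(X[!tr, , drop = FALSE])
      for (ki in seq_along(k_pcs)) {
        k <- min(k_pcs[ki], ncol(Ztr))
        m <- fit_binary(Ztr[, seq_len(k), drop = FALSE], y[tr], "logistic")
        fold_acc[f, ki] <- mean(predict_binary(m, Zte[, seq_len(k), drop = FALSE]) == y[!tr])
      }
    }
    acc[r, ] <- colMeans(fold_acc)
  }
  tibble(k = k_pcs, accuracy = colMeans(acc))
}
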