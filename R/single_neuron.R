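# Single-neuron pairwise discriminability.

# Folded, tie-corrected rank auROC: max(A, 1 - A) with A the midrank
# Mann-Whitney statistic. Used both as the degenerate-fit fallback and as
# the fast permutation statistic (it equals the fitted-logistic auROC; see
# fit_pairwise_auroc).
folded_rank_auroc <- function(values, positive) {
  a <- rank_auc_stat(values, positive)
  max(a, 1 - a)
}

#' Single-neuron pairwise odor discriminability (auROC)
#'
#' Fits an unregularized univariate logistic classifier to one neuron's
#' per-trial responses to two odors (the 60-trial Z-scored window means in
#' a standard session) and reports the area under the ROC of the fitted
#' scores, folded to `[0.5, 1]`. Because the logistic score is monotone in
#' the single input feature, this auROC is identical to the folded
#' tie-corrected Mann-Whitney rank statistic `max(A, 1 - A)`; when the fit
#' degenerates (perfect separation, zero variance) the rank statistic is
#' used directly and gives the same value.
#'
#' @param values Numeric vector of per-trial responses (both odors).
#' @param labels Two-level factor/character/logical of odor labels.
#' @param method `"train"` scores the fit on its own training trials (the
#'   default); `"cv"` scores held-out trials under stratified 5-fold CV.
#' @param folds,seed CV parameters for `method = "cv"`.
#' @return A one-row tibble: `auroc`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' fit_pairwise_auroc(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
fit_pairwise_auroc <- function(values, labels, method = c("train", "cv"),
                               folds = 5, seed = NULL) {
  method <- match.arg(method)
  lev <- unique(labels)
  if (length(lev) != 2) abort("`labels` must have exactly two classes")
  y <- labels == lev[2]
  if (sum(y) < 2 || sum(!y) < 2) abort("need >= 2 trials per class")

  score <- if (method == "train") {
    fit <- tryCatch(
      suppressWarnings(glm(y ~ values, family = binomial())),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(coef(fit)[2]) || coef(fit)[2] == 0) {
      values # rank-statistic fallback: identical folded auROC
    } else {
      # score through the fitted slope sign; evaluating b*x (rather than
      # taking glm's per-observation linear predictors) keeps tied inputs
      # tied to the last bit
      sign(coef(fit)[2]) * values
    }
  } else {
    fold <- stratified_folds(y, folds, seed)
    s <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- suppressWarnings(glm(y[tr] ~ values[tr], family = binomial()))
      s[!tr] <- coef(fit)[1] + coef(fit)[2] * values[!tr]
    }
    s
  }
  a <- rank_auc_stat(score, y)
  tibble(auroc = max(a, 1 - a), n1 = sum(y), n2 = sum(!y), method = method)
}

#' Permutation p-value for a pairwise auROC
#'
#' Compares the observed folded auROC against `n_shuffles` label
#' permutations (class counts preserved) and reports the add-one estimator
#' `p = (1 + #(shuffled >= observed)) / (n_shuffles + 1)`, so the smallest
#' attainable p is `1/(n_shuffles + 1)`. The permutation statistic is the
#' folded rank auROC, which equals the fitted-logistic auROC.
#'
#' @inheritParams fit_pairwise_auroc
#' @param n_shuffles Number of label permutations.
#' @param seed Integer seed.
#' @return A one-row tibble `auroc`, `null_p`, `n_shuffles`.
#' @export
shuffle_pvalue <- function(values, labels, n_shuffles = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lev <- unique(labels)
  if (length(lev) != 2) abort("`labels` must have exactly two classes")
  y <- labels == lev[2]
  obs <- folded_rank_auroc(values, y)
  n1 <- sum(y); ntot <- length(y)
  r <- rank(values)
  off <- n1 * (n1 + 1) / 2
  denom <- n1 * (ntot - n1)
  null <- vapply(seq_len(n_shuffles), function(s) {
    idx <- sample.int(ntot, n1)
    a <- (sum(r[idx]) - off) / denom
    max(a, 1 - a)
  }, numeric(1))
  p <- (1 + sum(null >= obs - 1e-12)) / (n_shuffles + 1)
  tibble(auroc = obs, null_p = p, n_shuffles = n_shuffles)
}

#' auROC table over all odor pairs for every neuron
#'
#' Computes [fit_pairwise_auroc()] (and optionally [shuffle_pvalue()]) for
#' each neuron and each unordered odor pair, on Z-scored late-odor window
#' means.
#'
#' @param tensor A [align_trials()] tensor.
#' @param window Feature window, default the last second of odor.
#' @param n_shuffles Permutations per record (0 skips the null).
#' @param pairs Optional tibble `odor_1`, `odor_2` restricting the pairs.
#' @param seed Integer seed for the permutation nulls.
#' @return A tibble `neuron`, `odor_1`, `odor_2`, `auroc`, and `null_p`,
#'   `n_shuffles` when requested.
#' @export
auroc_table <- function(tensor, window = c(1, 2), n_shuffles = 0,
                        pairs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials <- attr(tensor, "trials")
  odors <- attr(trials, "scheme")$odor
  if (is.null(pairs)) {
    cmb <- utils::combn(odors, 2)
    pairs <- tibble(odor_1 = cmb[1, ], odor_2 = cmb[2, ])
  }
  n <- dim(tensor)[1]
  res <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    tr <- which(trials$odor %in% c(pairs$odor_1[k], pairs$odor_2[k]))
    feat <- window_features(tensor, window, zscore = TRUE, trials = tr)
    labs <- trials$odor[tr]
    kept <- setdiff(seq_len(n), attr(feat, "excluded"))
    rows <- vector("list", length(kept))
    for (j in seq_along(kept)) {
      rec <- fit_pairwise_auroc(feat[j, ], labs)
      rec$neuron <- kept[j]
      if (n_shuffles > 0) {
        sp <- shuffle_pvalue(feat[j, ], labs, n_shuffles)
        rec$null_p <- sp$null_p
        rec$n_shuffles <- n_shuffles
      }
      rows[[j]] <- rec
    }
    res[[k]] <- dplyr::bind_rows(rows) |>
      dplyr::mutate(odor_1 = pairs$odor_1[k], odor_2 = pairs$odor_2[k])
  }
  dplyr::bind_rows(res) |>
    dplyr::select("neuron", "odor_1", "odor_2", dplyr::everything(), -"method", -"n1", -"n2")
}

#' Quadrant categorization of valence vs identity encoding
#'
#' Classifies neurons from two auROC values against a threshold: the
#' intervalence auROC (sucrose-paired vs control ketone) on the x-axis and
#' the intravalence auROC (the two sucrose-paired odors) on the y-axis.
#'
#' * `valence` -- inter > thr and intra <= thr,
#' * `identity` -- both > thr,
#' * `identity_S` -- intra > thr and inter <= thr,
#' * `uninformative` -- both <= thr.
#'
#' @param auroc_inter,auroc_intra Numeric vectors in `[0, 1]`.
#' @param threshold auROC threshold (0.75: halfway between chance and
#'   perfect).
#' @return A tibble of class `quadrant_table`: `auroc_inter`,
#'   `auroc_intra`, `category`, `threshold`.
#' @export
#' @examples
#' quadrant_classify(c(0.9, 0.9, 0.5), c(0.5, 0.9, 0.5))
quadrant_classify <- function(auroc_inter, auroc_intra, threshold = 0.75) {
  stopifnot(all(auroc_inter >= 0 & auroc_inter <= 1),
            all(auroc_intra >= 0 & auroc_intra <= 1))
  category <- dplyr::case_when(
    auroc_inter > threshold & auroc_intra <= threshold ~ "valence",
    auroc_inter > threshold & auroc_intra > threshold ~ "identity",
    auroc_inter <= threshold & auroc_intra > threshold ~ "identity_S",
    TRUE ~ "uninformative"
  )
  out <- tibble(auroc_inter = auroc_inter, auroc_intra = auroc_intra,
                category = factor(category, c("valence", "identity",
                                              "identity_S", "uninformative")),
                threshold = threshold)
  class(out) <- c("quadrant_table", class(out))
  out
}

#' Cross-validated 6-way confusion matrix for one neuron
#'
#' Trains a multinomial logistic classifier on a single neuron's per-trial
#' responses to all six odors under stratified cross-validation and
#' aggregates held-out predictions into a row-stochastic confusion matrix.
#'
#' @param values Per-trial response vector (all odors).
#' @param labels Odor label per trial (6 classes).
#' @param cv_folds Stratified folds.
#' @param seed Integer seed.
#' @return A `6 x 6` row-stochastic matrix, rows = true odor, columns =
#'   predicted odor.
#' @export
single_neuron_confusion <- function(values, labels, cv_folds = 5, seed = NULL) {
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < cv_folds)) abort("every class needs at least `cv_folds` trials")
  fold <- stratified_folds(labels, cv_folds, seed)
  pred <- character(length(labels))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    df <- data.frame(y = factor(labels[tr], classes), x = values[tr])
    fit <- nnet::multinom(y ~ x, df, trace = FALSE)
    pred[!tr] <- as.character(predict(fit, data.frame(x = values[!tr])))
  }
  cm <- table(factor(labels, classes), factor(pred, classes))
  cm <- unclass(cm / rowSums(cm))
  dimnames(cm) <- list(true = classes, predicted = classes)
  cm
}
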