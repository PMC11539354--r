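# Pooled trial-averaged response profiles and Ward clustering.

#' Build windowed response-profile features for clustering
#'
#' Trial-averages each neuron's dF/F per odor, Z-scores the averaged trace
#' per neuron across time (all six odor traces concatenated), then averages
#' three windows per odor -- first second of odor `[0, 1)`, last second of
#' odor `[1, 2)`, first second after odor `[2, 3)` -- yielding an 18-element
#' profile per neuron on a six-odor panel (odor-major column order).
#' Constant-activity neurons have no defined Z-score and are excluded with
#' a message.
#'
#' @param tensor A [align_trials()] tensor covering `[-2, 3)` s.
#' @param zscore_across `"time"` (default) Z-scores each neuron across the
#'   concatenated trial-averaged traces; `"features"` Z-scores the final
#'   18 features instead.
#' @return A `neurons x 18` matrix of class `cluster_features` with
#'   `excluded` attribute; rownames are neuron indices, colnames
#'   `odor.window`.
#' @export
build_cluster_features <- function(tensor, zscore_across = c("time", "features")) {
  zscore_across <- match.arg(zscore_across)
  ta <- attr(tensor, "time_axis")
  if (max(ta) < 3 - 1 / attr(tensor, "frame_rate") - 1e-9) {
    abort("tensor must cover [-2, 3) s around odor onset")
  }
  trials <- attr(tensor, "trials")
  odors <- attr(trials, "scheme")$odor
  n <- dim(tensor)[1]

  avg <- lapply(odors, function(o) {
    apply(tensor[, trials$odor == o, , drop = FALSE], c(1, 3), mean)
  }) # list of neurons x frames
  concat <- do.call(cbind, avg)
  mu <- rowMeans(concat)
  sdv <- apply(concat, 1, sd)
  excluded <- which(sdv == 0)

  windows <- list(early = c(0, 1), late = c(1, 2), post = c(2, 3))
  feats <- matrix(NA_real_, n, length(odors) * 3)
  colnames(feats) <- as.vector(t(outer(odors, names(windows), paste, sep = ".")))
  col <- 0
  for (o in seq_along(odors)) {
    z <- if (zscore_across == "time") (avg[[o]] - mu) / sdv else avg[[o]]
    for (w in windows) {
      col <- col + 1
      feats[, col] <- rowMeans(z[, frames_in_window(ta, w), drop = FALSE])
    }
  }
  if (zscore_across == "features") {
    mu2 <- rowMeans(feats); sd2 <- apply(feats, 1, sd)
    excluded <- which(sd2 == 0)
    feats <- (feats - mu2) / sd2
  }
  if (length(excluded)) {
    inform(sprintf("build_cluster_features: excluded %d constant neuron(s): %s",
                   length(excluded), paste(excluded, collapse = ", ")))
    feats <- feats[-excluded, , drop = FALSE]
    rownames(feats) <- setdiff(seq_len(n), excluded)
  } else {
    rownames(feats) <- seq_len(n)
  }
  structure(feats, excluded = excluded, class = c("cluster_features", "matrix", "array"))
}

#' Ward hierarchical clustering of response profiles
#'
#' Agglomerative clustering of profile features with Euclidean distance
#' and Ward linkage, cut at `n_clusters`. Cluster labels are renumbered by
#' ascending mean feature value so that the most inhibited profile is
#' cluster 1 -- a stable convention independent of agglomeration order.
#'
#' @param features A [build_cluster_features()] matrix (or any numeric
#'   `neurons x features` matrix).
#' @param n_clusters Number of clusters (6 for the switch paradigm, 3 for
#'   the lick-spout paradigm).
#' @param region Optional per-neuron region tag, carried into the output
#'   for composition summaries.
#' @return A tibble of class `cluster_assignment`: `neuron`, `cluster`
#'   (and `region` if given); attributes `tree` ([stats::hclust] object)
#'   and `merge_heights`.
#' @export
cluster_profiles <- function(features, n_clusters = 6, region = NULL) {
  if (n_clusters < 2) abort("`n_clusters` must be >= 2")
  if (nrow(features) < n_clusters) abort("fewer neurons than clusters")
  tree <- hclust(dist(features, method = "euclidean"), method = "ward.D2")
  raw <- cutree(tree, k = n_clusters)
  cluster_mean <- tapply(rowMeans(features), raw, mean)
  relabel <- rank(cluster_mean, ties.method = "first")
  cl <- as.integer(relabel[as.character(raw)])
  neuron <- if (!is.null(rownames(features))) {
    as.integer(rownames(features))
  } else {
    seq_len(nrow(features))
  }
  out <- tibble(neuron = neuron, cluster = cl)
  if (!is.null(region)) out$region <- region
  attr(out, "tree") <- tree
  attr(out, "merge_heights") <- tree$height
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Cluster composition by region
#'
#' Fraction of each cluster contributed by each region tag.
#'
#' @param assignment A [cluster_profiles()] result with a `region` column.
#' @return A tibble `cluster`, `region`, `n`, `fraction` (within cluster).
#' @export
cluster_composition <- function(assignment) {
  if (!"region" %in% names(assignment)) abort("assignment lacks a `region` column")
  assignment |>
    dplyr::count(.data$cluster, .data$region, name = "n") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
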