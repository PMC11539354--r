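# ggplot2 front-ends for the main result types.

#' @export
autoplot.distance_trajectories <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$distance,
                                       colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, 2), linetype = "dashed",
                        colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = "time from odor onset (s)",
                  y = "normalized pairwise distance", colour = "odor pair") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.generalization_matrix <- function(object, ...) {
  lev <- unique(object$train_pair)
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$test_pair, lev),
                                       factor(.data$train_pair, rev(lev)),
                                       fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, limits = c(0, 1),
                                  low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "testing pair", y = "training pair", fill = "accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.quadrant_table <- function(object, ...) {
  thr <- object$threshold[1]
  ggplot2::ggplot(object, ggplot2::aes(.data$auroc_inter, .data$auroc_intra,
                                       colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::coord_fixed(xlim = c(0.45, 1), ylim = c(0.45, 1)) +
    ggplot2::labs(x = "intervalence auROC", y = "intravalence auROC",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.time_accuracy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = c(0, 2), linetype = "dashed",
                        colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = "time from odor onset (s)", y = "CV accuracy") +
    ggplot2::theme_minimal()
}

#' Plot the decoupling scatter of per-neuron delta-R-squared losses
#'
#' @param record A [delta_r2_decoupling()] tibble.
#' @return A ggplot.
#' @export
plot_decoupling <- function(record) {
  ggplot2::ggplot(record, ggplot2::aes(.data$delta_r2_valence,
                                       .data$delta_r2_licking)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = expression(Delta * R^2 ~ "(contingency omitted)"),
                  y = expression(Delta * R^2 ~ "(licking omitted)")) +
    ggplot2::theme_minimal()
}
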