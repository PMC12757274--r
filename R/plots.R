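#' Plot an ROC curve
#'
#' @param object A `cp_roc` or `cp_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cp_roc
#' @export
autoplot.cp_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity (false-positive rate)",
      y = "Sensitivity (true-positive rate)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cp_roc
#' @method autoplot cp_eval
#' @export
autoplot.cp_eval <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::labs(title = sprintf("%s ROC (AUC = %.3f, threshold = %.4g)",
                                  object$score, object$auc, object$threshold))
}

#' Plot a fitted AUC response surface
#'
#' Raster of the polynomial surrogate over the unit square of reduced
#' weight coordinates, with the surrogate maximum marked.
#'
#' @param object A `cp_polysurface` or `cp_fit` object.
#' @param grid_n Raster resolution per axis.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cp_polysurface
#' @export
autoplot.cp_polysurface <- function(object, grid_n = 201L, ...) {
  g <- seq(0, 1, length.out = grid_n)
  grid <- tidyr::expand_grid(x = g, y = g)
  grid$q <- predict(object, grid)
  opt <- maximize_surface(object, grid_n = 201L)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$q)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$q), colour = "white",
                          linewidth = 0.2, bins = 12) +
    ggplot2::annotate("point", x = opt$x, y = opt$y, shape = 4, size = 3,
                      colour = "red") +
    ggplot2::scale_fill_viridis_c(name = "Q (AUC)") +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(
      x = "x (age weight)",
      y = "y (heart rate vs PaO2 weight)",
      title = sprintf("Polynomial AUC surface (order %d, R² = %.4f)",
                      object$order, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cp_polysurface
#' @method autoplot cp_fit
#' @export
autoplot.cp_fit <- function(object, grid_n = 201L, ...) {
  autoplot(object$surface, grid_n = grid_n) +
    ggplot2::annotate("point", x = object$reduced_opt[["x"]],
                      y = object$reduced_opt[["y"]], shape = 1, size = 4,
                      colour = "red")
}

#' Stacked-bar plot of 30-day outcome states
#'
#' Mirrors the usual presentation of risk-group trajectories: one stacked
#' bar per evaluation day (per risk group when present) partitioned into
#' hospitalized / discharged / dead proportions.
#'
#' @param object A `cp_outcome_table` from [outcome_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cp_outcome_table
#' @export
autoplot.cp_outcome_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("hospitalized", "discharged", "dead"),
    names_to = "state", values_to = "proportion"
  )
  long$state <- factor(long$state, levels = c("dead", "hospitalized", "discharged"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$day),
                                          y = .data$proportion,
                                          fill = .data$state)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::scale_fill_manual(values = c(dead = "#b2182b",
                                          hospitalized = "#92c5de",
                                          discharged = "#4dac26")) +
    ggplot2::labs(x = "Day after admission", y = "Proportion of group",
                  fill = "State") +
    ggplot2::theme_minimal()
  if ("risk_group" %in% names(long)) {
    p <- p + ggplot2::facet_wrap(~risk_group,
                                 labeller = ggplot2::label_both)
  }
  p
}
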