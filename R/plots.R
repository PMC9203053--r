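#' Plot a smoothed relatedness surface
#'
#' Raster of the smoothed z values over (target relatedness, cue
#' relatedness), with significance-cluster outlines when thresholds are
#' attached and the unsupported region dimmed.
#'
#' @param object A `retro_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot retro_surface
#' @export
autoplot.retro_surface <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "target relatedness", y = "cue relatedness",
                  fill = "Δ memorability") +
    ggplot2::theme_minimal()
  if ("in_cluster" %in% names(df) && any(df$in_cluster)) {
    p <- p + ggplot2::geom_point(
      data = df[df$in_cluster, ], shape = 3, size = 0.6,
      colour = "purple4", alpha = 0.7)
  }
  if (any(!df$support)) {
    p <- p + ggplot2::geom_tile(data = df[!df$support, ], fill = "white",
                                alpha = 0.55)
  }
  p
}

#' @rdname autoplot.retro_surface
#' @method autoplot retro_clusters
#' @export
autoplot.retro_clusters <- function(object, ...) {
  autoplot(object$surface, ...)
}

#' Plot an item-level regression with its confidence band
#'
#' @param object An [item_regression()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot item_regression
#' @export
autoplot.item_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(
      data = object$band,
      ggplot2::aes(x = .data$x, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(
      data = object$band,
      ggplot2::aes(x = .data$x, y = .data$fit), inherit.aes = FALSE,
      linewidth = 0.8) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "relatedness", y = "per-pair value") +
    ggplot2::theme_minimal()
}

#' Condition-level accuracy summary plot
#'
#' Per-subject mean base-test accuracy by condition, with condition means
#' overlaid, in the fixed condition order of the design.
#'
#' @param data A `retro_dataset` or outcomes tibble.
#' @return A ggplot.
#' @export
plot_condition_means <- function(data) {
  outcomes <- as_outcomes(data)
  per <- dplyr::summarise(
    dplyr::group_by(outcomes, .data$subject, .data$condition),
    accuracy = mean(.data$base_correct), .groups = "drop")
  per$condition <- factor(per$condition, levels = retro_conditions())
  ggplot2::ggplot(per, ggplot2::aes(x = .data$condition,
                                    y = .data$accuracy)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.2, size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 2.5) +
    ggplot2::labs(x = NULL, y = "base-test accuracy") +
    ggplot2::theme_minimal()
}

#' Dependence against relatedness with the mismatched-duo threshold line
#'
#' @param dep_table A [dependence_null()] table joined with coordinates, or
#'   any data frame with columns `d_true` and the chosen `x`.
#' @param x Relatedness column (tidy-eval; default `r_target`).
#' @return A ggplot with the mean mismatched-duo threshold as a dotted line.
#' @export
plot_dependence <- function(dep_table, x = r_target) {
  xq <- rlang::enquo(x)
  thr <- attr(dep_table, "mean_threshold")
  p <- ggplot2::ggplot(dep_table,
                       ggplot2::aes(x = !!xq, y = .data$d_true)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black", linewidth = 0.7) +
    ggplot2::labs(x = "relatedness", y = "dependence") +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dotted")
  }
  p
}

utils::globalVariables(c("r_target"))
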