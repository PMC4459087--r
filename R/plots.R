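# ggplot2 displays: the saturation curve, the calibration-placement bias
# profile, dated node ages with bootstrap intervals, and the young-vs-old
# node scatter across sensitivity runs.

#' Plot the expected distance-time curve of a saturation model
#'
#' @param model A [saturation_model()].
#' @param max_age Right edge of the time axis (MY).
#' @param cal_ages Optional calibration ages to mark on the curve.
#' @return A ggplot.
#' @export
plot_saturation_curve <- function(model, max_age = 70, cal_ages = NULL) {
  t <- seq(0, max_age, length.out = 400)
  df <- tibble::tibble(t = t, d = expected_distance(model, t))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$d)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_abline(slope = model$rate, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(xintercept = model$onset, linetype = "dotted") +
    ggplot2::labs(x = "divergence time (MY)",
                  y = "expected genetic distance (%)") +
    ggplot2::theme_minimal()
  if (!is.null(cal_ages)) {
    marks <- tibble::tibble(
      t = cal_ages, d = expected_distance(model, cal_ages),
      label = paste0("Con", cal_ages)
    )
    p <- p +
      ggplot2::geom_point(data = marks, size = 2) +
      ggplot2::geom_text(data = marks, ggplot2::aes(label = .data$label),
                         vjust = -0.8, size = 3)
  }
  p
}

#' Plot a calibration-placement bias profile
#'
#' Signed relative deviation of estimated from true node age across true ages,
#' as produced by [bias_profile()].
#'
#' @param profile A [bias_profile()] tibble (optionally row-bound over several
#'   calibration choices with an extra `calibration` column).
#' @return A ggplot.
#' @export
plot_bias_profile <- function(profile) {
  aes <- if ("calibration" %in% names(profile)) {
    ggplot2::aes(x = .data$true_age, y = .data$deviation_pct,
                 colour = .data$calibration)
  } else {
    ggplot2::aes(x = .data$true_age, y = .data$deviation_pct)
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "true divergence time (MY)",
                  y = "relative deviation of estimate (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot dated node ages with bootstrap intervals
#'
#' @param object A `dated_tree` from [date_tree()].
#' @param ... Unused.
#' @return A ggplot of point ages and 95% bootstrap intervals per node,
#'   ordered by age.
#' @method autoplot dated_tree
#' @export
autoplot.dated_tree <- function(object, ...) {
  df <- object$estimates
  df$node_rank <- rank(df$point_age, ties.method = "first")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$point_age, y = .data$node_rank)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, colour = "grey50"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "estimated node age (MY)", y = "node (ordered by age)") +
    ggplot2::theme_minimal()
}

#' Young-vs-old node scatter across sensitivity runs
#'
#' @param pairs Output of [scatter_pairs()].
#' @return A ggplot with one point per run; the reference run is highlighted.
#' @export
plot_scatter_pairs <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$old_age, y = .data$young_age)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$is_reference,
                                     colour = .data$is_reference), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 15)) +
    ggplot2::labs(x = "old node age (MY)", y = "young node age (MY)",
                  shape = "reference", colour = "reference") +
    ggplot2::theme_minimal()
}
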