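#' Plot power (or type I error) across the simulation grid
#'
#' @param report A [type1_power_suite()] result.
#' @param alpha Nominal level drawn as a dashed reference line.
#' @return A ggplot object: rejection rate vs allelic fold change, colored
#'   by method, faceted by sample size and expression level.
#' @export
plot_power <- function(report, alpha = 0.05) {
  ggplot2::ggplot(
    report,
    ggplot2::aes(x = factor(.data$aFC), y = .data$estimate,
                 colour = .data$method, group = .data$method)
  ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$n), cols = ggplot2::vars(.data$theta),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = "allelic fold change", y = "rejection rate",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot PIP calibration
#'
#' @param calib A [pip_calibration()] table (optionally with a `method`
#'   column for grouped display).
#' @return A ggplot object: observed causal fraction against the bin
#'   midpoint with the identity line.
#' @export
plot_calibration <- function(calib) {
  has_method <- "method" %in% names(calib)
  p <- ggplot2::ggplot(
    dplyr::filter(calib, .data$n > 0),
    ggplot2::aes(x = .data$bin_mid, y = .data$fraction)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.02
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "posterior inclusion probability (bin midpoint)",
                  y = "observed causal fraction") +
    ggplot2::theme_bw()
  if (has_method) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$method))
  } else {
    p + ggplot2::geom_point()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-variant PIPs of a fine-mapping fit
#'
#' @param object A `finemap_fit`.
#' @param ... Unused.
#' @return A ggplot object; credible-set members are highlighted.
#' @export
autoplot.finemap_fit <- function(object, ...) {
  d <- object$pip
  d$index <- seq_len(nrow(d))
  in_cs <- unique(unlist(object$credible_sets$variants))
  d$in_cs <- d$index %in% in_cs
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$pip,
                                  colour = .data$in_cs)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "outside CS", `TRUE` = "in 95% CS"), name = NULL
    ) +
    ggplot2::labs(x = "variant index", y = "PIP") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Plot held-out prediction performance
#'
#' @param detail The `detail` tibble of [prediction_suite()] or
#'   [crossval_evaluate()] output.
#' @return A ggplot boxplot of Pearson r by method.
#' @export
plot_prediction <- function(detail) {
  ggplot2::ggplot(detail, ggplot2::aes(x = .data$method, y = .data$r,
                                       fill = .data$method)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "held-out Pearson r") +
    ggplot2::theme_bw()
}
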