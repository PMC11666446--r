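#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the evaluation result types.
#'
#' * `independence_table`: tile map of within-bin correlations by scaler,
#'   sex, and workload bin, with significant cells outlined.
#' * `calibration_report`: per-cell calibration slopes with 95% CIs
#'   against the ideal slope of 1 (the +/- 0.05 band shaded).
#' * `wl_comparison`: mean workload discrepancy by workload decile.
#' * `contrast_report`: absolute Cohen's D by contrast and scaling
#'   standard.
#'
#' @param object An evaluation result.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ebmscale-autoplot
NULL

#' @rdname ebmscale-autoplot
#' @method autoplot independence_table
#' @export
autoplot.independence_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$wl_bin <- factor(df$wl_bin, levels = unique(df$wl_bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wl_bin, y = .data$scaler,
                                   fill = .data$r)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_tile(
      data = df[df$significant, , drop = FALSE],
      fill = NA, colour = "black", linewidth = 0.8
    ) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::facet_wrap(~sex, ncol = 1, scales = "free_x") +
    ggplot2::labs(
      x = "Workload bin (METs)", y = NULL, fill = "r",
      title = "Body-size independence of indexed VO2peak",
      subtitle = "Outlined cells: p below the display threshold"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname ebmscale-autoplot
#' @method autoplot calibration_report
#' @export
autoplot.calibration_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$cell <- interaction(df$age_band, df$bmi_band, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$slope)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0.95,
                      ymax = 1.05, alpha = 0.15) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(
      x = "Age band / BMI band", y = "Calibration slope",
      title = sprintf("Calibration of the %s-standard prediction",
                      attr(object, "standard"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname ebmscale-autoplot
#' @method autoplot wl_comparison
#' @export
autoplot.wl_comparison <- function(object, ...) {
  ggplot2::ggplot(object$by_bin,
                  ggplot2::aes(x = .data$wl_ebm_mean, y = .data$mean_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "EBM-based workload (METs, decile mean)",
      y = "WL_ebm - WL_kokkinos (METs)",
      title = "Workload formula discrepancy by intensity"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname ebmscale-autoplot
#' @method autoplot contrast_report
#' @export
autoplot.contrast_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast,
                                   y = abs(.data$cohens_d),
                                   fill = .data$standard)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "|Cohen's D|", fill = "Scaling standard",
      title = "Subgroup effect sizes by scaling standard"
    ) +
    ggplot2::theme_minimal()
}
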