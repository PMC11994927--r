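# ggplot2 displays for the main result types.

#' @exportS3Method
autoplot.pk_sim <- function(object, ...) {
  drug <- if (!is.null(object$model$drug)) object$model$drug$name else "drug"
  ggplot2::ggplot(object$timecourse,
                  ggplot2::aes(x = .data$time_h, y = .data$conc_ng_ml)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)",
                  title = paste0(drug, ", ", object$regimen$dose_mg, " mg")) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.uge_sim <- function(object, ...) {
  ggplot2::ggplot(object$timecourse,
                  ggplot2::aes(x = .data$time_h, y = .data$cumulative_uge_g)) +
    ggplot2::geom_line(color = "#b2182b") +
    ggplot2::labs(x = "Time (h)", y = "Cumulative UGE (g)",
                  title = sprintf("GFR %.0f mL/min", object$gfr_ml_min)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.uge_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = paste0(.data$drug, " ", .data$dose_mg, " mg"),
    y = .data$mean_uge_g)) +
    ggplot2::geom_col(fill = "#74add1") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q05_uge_g,
                                        ymax = .data$q95_uge_g), width = 0.3) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "24-h UGE (g), mean and 90% interval") +
    ggplot2::theme_minimal()
}

#' Goodness-of-fit plot for paired observed/predicted values
#'
#' Observed vs predicted on log axes, with the identity line and the 0.8-1.3
#' and 0.5-2 fold-error bands.
#'
#' @param pairs Data frame with `observed`, `predicted` and optionally `drug`.
#' @return A ggplot object.
#' @export
plot_goodness_of_fit <- function(pairs) {
  check_pairs(pairs)
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$observed,
                                           y = .data$predicted))
  if ("drug" %in% names(pairs)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$drug), alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = log10(c(0.8, 1.3)),
                         linetype = "dotted", color = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = log10(c(0.5, 2)),
                         linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Observed", y = "Predicted") +
    ggplot2::theme_minimal()
}

#' Population prediction-band plot
#'
#' @param bands A [population_bands()] tibble.
#' @param observed Optional data frame of observed points (`time_h`, `value`).
#' @return A ggplot object.
#' @export
plot_population_bands <- function(bands, observed = NULL) {
  p <- ggplot2::ggplot(bands, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "#74add1", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), color = "#2166ac") +
    ggplot2::labs(x = "Time (h)", y = "Value") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(data = observed,
                                 ggplot2::aes(y = .data$value), size = 1)
  }
  p
}
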