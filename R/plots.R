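#' Coefficient plot for a fitted soil temperature model
#'
#' @param object An `fc_soil_fit`.
#' @param ... Unused.
#' @return A ggplot: standardized fixed coefficients with 95% intervals.
#' @export
autoplot.fc_soil_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$estimate, y = stats::reorder(.data$term, .data$estimate)
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "standardized coefficient (degC per SD)", y = NULL,
      title = "Soil temperature model: fixed effects"
    )
}

#' Observed vs predicted validation scatter
#'
#' @param df Tibble with observed and predicted columns.
#' @param observed,predicted Column names.
#' @return A ggplot with the 1:1 line dashed.
#' @export
plot_validation <- function(df, observed = "soilT", predicted = ".pred") {
  ggplot2::ggplot(df, ggplot2::aes(.data[[predicted]], .data[[observed]])) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "predicted soil temperature (degC)",
                  y = "observed soil temperature (degC)")
}

#' Buffering-potential class distribution
#'
#' @param summary_buffering The `buffering` table from
#'   [summarize_buffering()].
#' @return A ggplot of class percentages by band and distance class.
#' @export
plot_buffering <- function(summary_buffering) {
  ggplot2::ggplot(summary_buffering, ggplot2::aes(
    x = .data$distance_class, y = .data$percent, fill = .data$t_bp_class
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = "distance from glacier (m)", y = "percent of points",
                  fill = "T_bp class")
}
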