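#' Coefficient plot for a fitted share model
#'
#' Point estimates with approximate 95% Wald intervals
#' (estimate +/- 1.96 robust SE), one panel per crop.
#'
#' @param object A [fit_qmle()] object with a covariance attached.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qmle_fit
#' @export
autoplot.qmle_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~crop, scales = "free_x") +
    ggplot2::labs(x = "coefficient (95% Wald interval)", y = NULL)
}

#' Calibration scatter of predicted versus observed unit shares
#'
#' One point per unit, the 45-degree line of perfect calibration, and
#' the OLS fit of observed on predicted.
#'
#' @param predicted,observed Aligned numeric share vectors, or tibbles
#'   with `unit`, `share` (and optionally `crop`) columns as accepted
#'   by [share_rmse()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(predicted, observed) {
  if (is.data.frame(predicted)) {
    keys <- intersect(c("unit", "crop"), names(predicted))
    m <- dplyr::inner_join(dplyr::rename(predicted, predicted = "share"),
                           dplyr::rename(observed, observed = "share"),
                           by = keys)
  } else {
    m <- tibble::tibble(predicted = predicted, observed = observed)
  }
  p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$predicted,
                                       y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::labs(x = "predicted share", y = "observed share")
  if ("crop" %in% names(m)) p <- p + ggplot2::facet_wrap(~crop)
  p
}
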