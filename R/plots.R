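#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   geom_ribbon labs facet_wrap theme_minimal
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a channel signal
#'
#' Luminosity time series with interpolated (tracking-invalid) samples marked.
#'
#' @param object a [channel_signal()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.channel_signal <- function(object, ...) {
  ggplot(object, aes(x = .data$t_sec, y = .data$value)) +
    geom_line(colour = "grey30") +
    geom_point(data = object[!object$valid, ], colour = "firebrick", size = 0.8) +
    labs(x = "time (s)",
         y = sprintf("%s-channel luminosity (detrended)", attr(object, "channel"))) +
    theme_minimal()
}

#' Plot a spectral estimate
#'
#' In-band amplitude spectrum with the interpolated peak marked.
#'
#' @param object a `spectral_estimate`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.spectral_estimate <- function(object, ...) {
  ggplot(object$spectrum, aes(x = .data$frequency, y = .data$magnitude)) +
    geom_line() +
    geom_point(data = tibble(frequency = object$f_peak, magnitude = object$amplitude),
               colour = "firebrick") +
    labs(x = "frequency (Hz)", y = "amplitude",
         title = sprintf("%s band: %.2f Hz (%.0f per minute)",
                         object$band$name, object$f_peak, 60 * object$f_peak)) +
    theme_minimal()
}

#' Plot a through-origin regression
#'
#' Observed vs fitted values with the prediction band and flagged outliers.
#'
#' @param object a `to_regression`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.to_regression <- function(object, ...) {
  d <- object$data[order(object$data$x), ]
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_ribbon(aes(ymin = .data$fitted - .data$pi_half_width,
                    ymax = .data$fitted + .data$pi_half_width),
                fill = "grey85") +
    geom_abline(slope = object$slope, intercept = 0, colour = "steelblue") +
    geom_point(aes(colour = .data$outlier), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey20", `TRUE` = "firebrick"),
                                 guide = "none") +
    labs(x = "observed", y = "predicted",
         title = sprintf("slope %.3f, R %.3f, RMSE %.3f, %d/%d outliers",
                         object$slope, object$r, object$rmse,
                         object$outlier_count, object$n)) +
    theme_minimal()
}

#' Plot a vitals fit
#'
#' Predicted against true heart and respiration rates, faceted by target,
#' with the identity line.
#'
#' @param object a `vitals_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.vitals_fit <- function(object, ...) {
  p <- object$predictions
  d <- dplyr::bind_rows(
    tibble(target = "HR (BPM)", truth = p$hr_true, predicted = p$hr_pred, stage = p$stage),
    tibble(target = "RR (BrPM)", truth = p$rr_true, predicted = p$rr_pred, stage = p$stage)
  )
  ggplot(d, aes(x = .data$truth, y = .data$predicted, colour = .data$stage)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_point(size = 1) +
    facet_wrap(~target, scales = "free") +
    labs(x = "reference", y = "model estimate") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
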