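#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_errorbar
#'   labs theme_minimal scale_y_log10
#' @export
ggplot2::autoplot

#' Plot a recording as a family of current sweeps
#'
#' @param object A `sweep_recording`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_recording <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$time_ms, y = .data$current_nA,
                 group = .data$sweep, colour = factor(.data$sweep))) +
    geom_line(linewidth = 0.3, show.legend = FALSE) +
    labs(x = "Time (ms)", y = "Current (nA)",
         title = sprintf("%s | %s", object$provenance$model_name,
                         object$protocol$name)) +
    theme_minimal()
}

#' Plot a GV or SSI curve with its Boltzmann fit
#'
#' @param object A `gv_curve` or `ssi_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vclamp_curve <- function(object, ...) {
  vv <- seq(min(object$data$voltage), max(object$data$voltage), length.out = 200)
  fit_df <- tibble::tibble(voltage = vv, value = predict(object$fit, vv))
  ylab <- if (inherits(object, "gv_curve")) "G / Gmax" else "Availability"
  p <- ggplot(object$data, aes(x = .data$voltage, y = .data$mean)) +
    geom_line(data = fit_df, aes(y = .data$value), colour = "grey40") +
    geom_point() +
    labs(x = "Voltage (mV)", y = ylab,
         subtitle = sprintf("V50 = %.1f mV, s = %.1f mV", object$v50, object$s)) +
    theme_minimal()
  if (any(is.finite(object$data$sem))) {
    p <- p + geom_errorbar(aes(ymin = .data$mean - .data$sem,
                               ymax = .data$mean + .data$sem), width = 2)
  }
  p
}

#' Plot deactivation time constants against tail voltage (semi-log)
#'
#' @param tau_curve Tibble from [deactivation_tau_curve()].
#' @return A ggplot with log-scaled tau axis; linearity reflects the
#'   voltage dependence of the closing transition.
#' @export
plot_deactivation_tau <- function(tau_curve) {
  ggplot(tau_curve, aes(x = .data$voltage, y = .data$tau)) +
    geom_point() + geom_line() +
    scale_y_log10() +
    labs(x = "Tail voltage (mV)", y = "Deactivation tau (ms)") +
    theme_minimal()
}
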