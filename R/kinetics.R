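#' Sigmoidal activation delay and late-phase time constant
#'
#' Quantifies activation time course in two parameters: a single exponential
#' is fitted to the late phase of the current rise (samples at or above 50%
#' of the final rise), and the delay is the time between the start of the
#' voltage pulse and the point where the fitted exponential intercepts the
#' zero-current baseline (closed form
#' `t_zero = t50 - tau * log(-i_ss / b)`). A mono-exponential rise from zero
#' has zero delay; multiple rate-limiting closed-closed transitions give a
#' positive delay.
#'
#' @param time Time vector, ms.
#' @param current Current vector, nA (baseline-subtracted; the zero line is
#'   the pre-pulse baseline).
#' @param t_pulse_start Start of the voltage pulse, ms.
#' @param t_pulse_end Optional end of the analysis window, ms (defaults to
#'   the end of the trace).
#' @return A list: `delay` (ms, >= 0 up to fit tolerance), `tau_late` (ms),
#'   `fit` (the late-phase `exp_fit`), `i_ss`.
#' @export
activation_delay_and_tau <- function(time, current, t_pulse_start,
                                     t_pulse_end = max(time)) {
  win <- time >= t_pulse_start & time <= t_pulse_end
  t <- time[win]; i <- current[win]
  if (length(t) < 8) abort("Activation window too short.")
  sgn <- sign(mean(tail(i, max(3, length(i) %/% 10))))
  if (sgn == 0) abort("Flat activation trace.")
  i <- i * sgn
  i_final <- mean(tail(i, max(3, length(i) %/% 20)))
  if (max(i) < 0.9 * i_final) abort("Trace does not reach 90% of its plateau.")
  late <- which(i >= 0.5 * i_final)
  if (!length(late) || length(late) < 4) abort("Late activation phase too short to fit.")
  late <- late[late >= late[[1]]]  # contiguous from the half-rise crossing
  fit <- fit_exponential(t[late], i[late])
  if (!fit$converged) abort("Late-phase exponential fit failed to converge.")
  i_ss <- fit$i_i
  b <- fit$a  # amplitude at window start t50 (negative for a rise)
  if (b >= 0 || i_ss <= 0 || -i_ss / b < 1) {
    abort("Fitted late-phase exponential never crosses the zero-current line; delay undefined.")
  }
  t50 <- fit$t0
  t_zero <- t50 - fit$tau * log(-i_ss / b)
  list(delay = t_zero - t_pulse_start, tau_late = fit$tau, fit = fit, i_ss = sgn * i_ss)
}

#' Isochronal tail-current amplitude by back-extrapolation
#'
#' Fits a single exponential to the tail-current decay after a settling
#' blank and back-extrapolates to the instant of repolarization, giving the
#' amplitude proportional to the conductance at the end of the preceding
#' step, robust to blanked capacitive samples.
#'
#' @param time Time vector, ms.
#' @param current Current vector, nA.
#' @param t_repol Time of repolarization (tail-epoch start), ms.
#' @param blank Settling blank excluded after `t_repol`, ms.
#' @param window Length of the fitted decay window, ms (default: to the end
#'   of the trace).
#' @return A list: `amplitude` (nA, signed, extrapolated to `t_repol`),
#'   `tau` (ms), `i_i` (offset, nA), `fit`.
#' @export
tail_amplitude <- function(time, current, t_repol, blank = 0.3, window = NULL) {
  t_end <- if (is.null(window)) max(time) else t_repol + blank + window
  win <- time >= t_repol + blank - 1e-9 & time <= t_end + 1e-9
  if (sum(win) < 4) abort("No tail decay window after `t_repol`.")
  t <- time[win]; i <- current[win]
  span <- diff(range(i))
  if (span < 1e-9 * max(abs(i), 1e-9) || max(abs(i)) < 1e-12) {
    # channel closed at step end: no decaying component
    return(list(amplitude = 0, tau = NA_real_, i_i = mean(i), fit = NULL))
  }
  fit <- fit_exponential(t, i)
  if (!fit$converged) abort("Tail exponential fit failed to converge.")
  # amplitude referenced to t_repol rather than the post-blank window start
  amp <- fit$a * exp((fit$t0 - t_repol) / fit$tau)
  list(amplitude = amp, tau = fit$tau, i_i = fit$i_i, fit = fit)
}

#' Deactivation time constants across tail voltages
#'
#' Fits the tail-current decay at each tail voltage of a deactivation
#' protocol with a single exponential. For a channel whose closing time
#' constant depends e-fold-per-fixed-voltage on V, `log(tau)` is linear in
#' voltage; the returned attribute `loglinear_r2` quantifies that linearity.
#'
#' @param recording A `sweep_recording` from the `deactivation_tails`
#'   protocol (hold, activating step, sweep-varying tail).
#' @param blank Settling blank after repolarization, ms.
#' @return A tibble with `voltage` (mV) and `tau` (ms), one row per sweep,
#'   with attribute `loglinear_r2`.
#' @export
deactivation_tau_curve <- function(recording, blank = 0.3) {
  stopifnot(inherits(recording, "sweep_recording"))
  protocol <- recording$protocol
  tail_epoch <- nrow(protocol$epochs)
  t_repol <- sum(protocol$epochs$duration[-tail_epoch])
  res <- purrr::map_dfr(seq_len(protocol$n_sweeps), function(sw) {
    v_tail <- epoch_voltages(protocol, sw)[[tail_epoch]]
    ta <- tail_amplitude(recording$time, recording$currents[sw, ], t_repol,
                         blank = blank)
    tibble::tibble(voltage = v_tail, tau = ta$tau)
  })
  fit <- stats::lm(log(tau) ~ voltage, data = res)
  attr(res, "loglinear_r2") <- summary(fit)$r.squared
  res
}
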