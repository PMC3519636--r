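# Levenberg-Marquardt least squares via minpack.lm::nls.lm with box
# constraints. Works on residual functions directly, which stays robust when
# the model fits the data to machine precision (noiseless synthetic traces).
.lm_fit <- function(par, resid_fn, lower = NULL, upper = NULL, maxiter = 200) {
  out <- tryCatch(
    minpack.lm::nls.lm(
      par = par, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           maxfev = 100 * maxiter)),
    error = function(e) e)
  if (inherits(out, "error")) {
    return(list(par = par, rss = NA_real_, converged = FALSE,
                diagnostics = conditionMessage(out)))
  }
  list(par = as.list(out$par), rss = sum(out$fvec^2),
       converged = out$info %in% 1:4 && !anyNA(unlist(out$par)),
       diagnostics = if (out$info %in% 1:4) NULL else out$message)
}

#' Boltzmann fit of conductance-voltage or availability data
#'
#' Least-squares fit of `g(V) = (a1 - a2) / (1 + exp((V - v50)/s)) + a2`,
#' where `a1` is the hyperpolarized and `a2` the depolarized asymptote, `v50`
#' the midpoint and `s > 0` the slope factor. With `normalized = TRUE` the
#' asymptotes are fixed by direction: an increasing (activation) curve is
#' constrained to 0 -> 1; a decreasing (availability) curve to
#' 1 -> pedestal, the pedestal remaining free to absorb partial
#' inactivation. Direction is inferred from the data unless given.
#'
#' @param v Voltages, mV.
#' @param g Conductances (or normalized fractions).
#' @param normalized Fix the asymptotes as described above.
#' @param direction `"auto"`, `"increasing"` or `"decreasing"`.
#' @return A `boltzmann_fit` object with fields `a1`, `a2`, `v50`, `s`,
#'   `rss`, `converged`, `low_confidence`, and the data.
#' @examples
#' v <- seq(-60, 60, 10)
#' g <- 1 / (1 + exp(-(v - -19.5) / 5.7))
#' fit_boltzmann(v, g, normalized = TRUE)
#' @export
fit_boltzmann <- function(v, g, normalized = FALSE,
                          direction = c("auto", "increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (length(v) != length(g)) abort("`v` and `g` must have equal length.")
  if (length(v) < 4) abort("Boltzmann fit needs at least 4 points.")
  ok <- is.finite(v) & is.finite(g)
  v <- v[ok]; g <- g[ok]
  if (length(v) < 4) abort("Boltzmann fit needs at least 4 finite points.")

  if (direction == "auto") {
    direction <- if (stats::cor(v, g) >= 0) "increasing" else "decreasing"
  }
  increasing <- direction == "increasing"

  span <- diff(range(g))
  low_confidence <- length(v) < 5 || span < 1e-12
  # initial guesses: v50 at the half-range crossing, s = 5 mV
  half <- min(g) + span / 2
  v50_0 <- v[which.min(abs(g - half))]
  s0 <- 5

  df <- data.frame(v = v, g = g)
  if (normalized) {
    if (increasing) {
      # 0 -> 1
      fit <- .lm_fit(
        list(v50 = v50_0, s = s0),
        function(p) g - 1 / (1 + exp(-(v - p$v50) / p$s)),
        lower = c(min(v) - 100, 1e-3), upper = c(max(v) + 100, 200))
      p <- list(a1 = 0, a2 = 1, v50 = fit$par$v50, s = fit$par$s)
    } else {
      # 1 -> pedestal (free)
      ped0 <- max(0, min(g))
      fit <- .lm_fit(
        list(v50 = v50_0, s = s0, ped = ped0),
        function(p) g - (p$ped + (1 - p$ped) / (1 + exp((v - p$v50) / p$s))),
        lower = c(min(v) - 100, 1e-3, 0), upper = c(max(v) + 100, 200, 1))
      p <- list(a1 = 1, a2 = fit$par$ped, v50 = fit$par$v50, s = fit$par$s)
    }
  } else {
    a1_0 <- if (increasing) min(g) else max(g)
    a2_0 <- if (increasing) max(g) else min(g)
    fit <- .lm_fit(
      list(a1 = a1_0, a2 = a2_0, v50 = v50_0, s = s0),
      function(p) g - ((p$a1 - p$a2) / (1 + exp((v - p$v50) / p$s)) + p$a2),
      lower = c(-Inf, -Inf, min(v) - 100, 1e-3),
      upper = c(Inf, Inf, max(v) + 100, 200))
    p <- fit$par
  }

  if (!fit$converged) {
    return(structure(
      list(a1 = NA_real_, a2 = NA_real_, v50 = NA_real_, s = NA_real_,
           rss = fit$rss, converged = FALSE, low_confidence = low_confidence,
           normalized = normalized, direction = direction,
           diagnostics = fit$diagnostics, data = df),
      class = "boltzmann_fit"))
  }
  structure(
    list(a1 = p$a1, a2 = p$a2, v50 = p$v50, s = p$s,
         rss = fit$rss, converged = TRUE,
         low_confidence = low_confidence, normalized = normalized,
         direction = direction, diagnostics = NULL, data = df),
    class = "boltzmann_fit")
}

#' Evaluate a fitted Boltzmann curve
#' @param object A `boltzmann_fit`.
#' @param v Voltages, mV.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.boltzmann_fit <- function(object, v = object$data$v, ...) {
  (object$a1 - object$a2) / (1 + exp((v - object$v50) / object$s)) + object$a2
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> V50 = %.2f mV, s = %.2f mV (a1 %.3g, a2 %.3g), rss %.3g%s\n",
              x$v50, x$s, x$a1, x$a2, x$rss,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Single-exponential fit of a current relaxation
#'
#' Fits `I(t) = i_i + a * exp(-(t - t[1]) / tau)` by least squares. Applies
#' to decays (a > 0 toward smaller currents after sign normalization) and
#' rises (a < 0). Time is referenced to the first sample of the window, so
#' `a` is the amplitude at window start.
#'
#' @param t Time, ms.
#' @param i Current, nA.
#' @return An `exp_fit` with fields `i_i`, `a`, `tau`, `rss`, `converged`.
#' @examples
#' t <- seq(0, 20, 0.05)
#' fit_exponential(t, 5 * exp(-t / 2.4))$tau
#' @export
fit_exponential <- function(t, i) {
  if (length(t) != length(i)) abort("`t` and `i` must have equal length.")
  if (length(t) < 4) abort("Exponential fit needs at least 4 samples.")
  span <- diff(range(i))
  if (span < 1e-12 * max(abs(i), 1e-12) || span == 0) {
    abort("Degenerate fit: trace is flat.")
  }
  t0 <- t[[1]]
  tr <- t - t0
  i_inf0 <- mean(tail(i, max(3, length(i) %/% 20)))
  a0 <- i[[1]] - i_inf0
  # tau guess: time to reach (1 - 1/e) of the span
  target <- i[[1]] - (1 - exp(-1)) * (i[[1]] - i_inf0)
  k <- which(if (a0 > 0) i <= target else i >= target)[1]
  tau0 <- if (!is.na(k) && tr[[k]] > 0) tr[[k]] else max(tr) / 3
  fit <- .lm_fit(
    list(i_i = i_inf0, a = a0, tau = tau0),
    function(p) i - (p$i_i + p$a * exp(-tr / p$tau)),
    lower = c(-Inf, -Inf, 1e-6), upper = c(Inf, Inf, 1e7))
  if (!fit$converged) {
    return(structure(list(i_i = NA_real_, a = NA_real_, tau = NA_real_,
                          rss = fit$rss, converged = FALSE, t0 = t0,
                          diagnostics = fit$diagnostics,
                          data = data.frame(t = t, i = i)),
                     class = "exp_fit"))
  }
  structure(list(i_i = fit$par$i_i, a = fit$par$a, tau = fit$par$tau,
                 rss = fit$rss, converged = TRUE, t0 = t0,
                 diagnostics = NULL, data = data.frame(t = t, i = i)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> tau = %.3f ms, a = %.3g nA, i_i = %.3g nA, rss %.3g%s\n",
              x$tau, x$a, x$i_i, x$rss,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @rdname predict.boltzmann_fit
#' @param t Times (for exponential fits), ms.
#' @export
predict.exp_fit <- function(object, t = object$data$t, ...) {
  object$i_i + object$a * exp(-(t - object$t0) / object$tau)
}

#' Double-exponential fit of an inactivation decay
#'
#' Fits `I(t) = i_i + a1 * exp(-t'/tau1) + a2 * exp(-t'/tau2)` with
#' `tau1 < tau2` (fast component first) and reports fractional amplitudes
#' `f_j = |a_j| / (|a1| + |a2|)`.
#'
#' @inheritParams fit_exponential
#' @return A `double_exp_fit` with fields `i_i`, `a1`, `tau1`, `a2`, `tau2`,
#'   `f1`, `f2`, `rss`, `converged`.
#' @export
fit_double_exponential <- function(t, i) {
  if (length(t) != length(i)) abort("`t` and `i` must have equal length.")
  if (length(t) < 6) abort("Double-exponential fit needs at least 6 samples.")
  span <- diff(range(i))
  if (span < 1e-12 * max(abs(i), 1e-12) || span == 0) {
    abort("Degenerate fit: trace is flat.")
  }
  t0 <- t[[1]]
  tr <- t - t0
  # peel: slow component from the tail two-thirds, fast from the early
  # residual; a fully decayed (flat) tail falls back to the whole window
  slow <- tryCatch(fit_exponential(t[tr >= max(tr) / 3], i[tr >= max(tr) / 3]),
                   error = function(e) NULL)
  if (is.null(slow) || !slow$converged) slow <- fit_exponential(t, i)
  resid_early <- i - predict(slow, t)
  a2_0 <- slow$a * exp((t0 - slow$t0) / slow$tau)
  tau2_0 <- slow$tau
  early_n <- max(6L, sum(tr <= tau2_0 / 3))
  fast <- tryCatch(fit_exponential(t[seq_len(early_n)], resid_early[seq_len(early_n)]),
                   error = function(e) NULL)
  a1_0 <- if (!is.null(fast) && fast$converged) fast$a else (i[[1]] - slow$i_i - a2_0)
  tau1_0 <- if (!is.null(fast) && fast$converged) min(fast$tau, tau2_0 / 4) else tau2_0 / 10
  if (abs(a1_0) < 1e-9 * max(abs(i))) a1_0 <- sign(a2_0 + 1e-30) * 0.05 * abs(a2_0)

  fit <- .lm_fit(
    list(i_i = slow$i_i, a1 = a1_0, tau1 = max(tau1_0, 1e-3),
         a2 = a2_0, tau2 = tau2_0),
    function(p) i - (p$i_i + p$a1 * exp(-tr / p$tau1) + p$a2 * exp(-tr / p$tau2)),
    lower = c(-Inf, -Inf, 1e-6, -Inf, 1e-6), upper = rep(Inf, 5),
    maxiter = 400)
  if (!fit$converged) {
    return(structure(list(i_i = NA_real_, a1 = NA_real_, tau1 = NA_real_,
                          a2 = NA_real_, tau2 = NA_real_, f1 = NA_real_,
                          f2 = NA_real_, rss = NA_real_, converged = FALSE,
                          t0 = t0, diagnostics = fit$diagnostics,
                          data = data.frame(t = t, i = i)),
                     class = "double_exp_fit"))
  }
  cf <- fit$par
  comps <- data.frame(a = c(cf$a1, cf$a2), tau = c(cf$tau1, cf$tau2))
  comps <- comps[order(comps$tau), ]
  fsum <- sum(abs(comps$a))
  structure(list(
    i_i = cf[["i_i"]],
    a1 = comps$a[[1]], tau1 = comps$tau[[1]],
    a2 = comps$a[[2]], tau2 = comps$tau[[2]],
    f1 = abs(comps$a[[1]]) / fsum, f2 = abs(comps$a[[2]]) / fsum,
    rss = fit$rss, converged = TRUE, t0 = t0,
    diagnostics = NULL, data = data.frame(t = t, i = i)),
    class = "double_exp_fit")
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf("<double_exp_fit> tau1 = %.2f ms (%.2f), tau2 = %.2f ms (%.2f), rss %.3g%s\n",
              x$tau1, x$f1, x$tau2, x$f2, x$rss,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @rdname predict.boltzmann_fit
#' @export
predict.double_exp_fit <- function(object, t = object$data$t, ...) {
  tr <- t - object$t0
  object$i_i + object$a1 * exp(-tr / object$tau1) + object$a2 * exp(-tr / object$tau2)
}

#' Choose between single- and double-exponential inactivation
#'
#' Fits both models to a decay and selects the double-exponential only when
#' (i) a nested-model F-test rejects the single exponential at `alpha`,
#' (ii) the two time constants are well separated (`tau2/tau1 > 3`), and
#' (iii) the minor component carries a non-negligible fractional amplitude
#' (>= `min_fraction`); the last guard keeps the rule meaningful on
#' noiseless synthetic data, where the F statistic alone diverges for
#' arbitrarily small true second components. Ties prefer the simpler model.
#'
#' @inheritParams fit_exponential
#' @param alpha F-test significance level.
#' @param tau_ratio_min Required separation `tau2/tau1`.
#' @param min_fraction Required minor-component fractional amplitude.
#' @return An `inact_model_selection`: list with `n_components` (1 or 2),
#'   `single`, `double`, `f_stat`, `p_value`.
#' @export
select_inactivation_model <- function(t, i, alpha = 0.01, tau_ratio_min = 3,
                                      min_fraction = 0.05) {
  single <- fit_exponential(t, i)
  double <- tryCatch(fit_double_exponential(t, i), error = function(e) {
    structure(list(converged = FALSE, diagnostics = conditionMessage(e)),
              class = "double_exp_fit")
  })
  n <- length(t)
  out <- list(single = single, double = double, f_stat = NA_real_,
              p_value = NA_real_, n_components = 1L)
  if (!double$converged || !single$converged) {
    if (!single$converged && double$converged) out$n_components <- 2L
    return(structure(out, class = "inact_model_selection"))
  }
  rss1 <- single$rss
  rss2 <- double$rss
  df2 <- n - 5
  scale <- sum(i^2)
  if (rss2 <= 1e-18 * max(scale, 1e-12)) {
    # numerically perfect double fit: compare rss1 against numerical zero
    f_stat <- Inf
    p <- if (rss1 <= 1e-15 * max(scale, 1e-12)) 1 else 0
  } else {
    f_stat <- ((rss1 - rss2) / 2) / (rss2 / df2)
    p <- pf(f_stat, 2, df2, lower.tail = FALSE)
  }
  out$f_stat <- f_stat
  out$p_value <- p
  two <- (p < alpha) &&
    (double$tau2 / double$tau1 > tau_ratio_min) &&
    (min(double$f1, double$f2) >= min_fraction)
  out$n_components <- if (isTRUE(two)) 2L else 1L
  structure(out, class = "inact_model_selection")
}

#' @export
print.inact_model_selection <- function(x, ...) {
  cat(sprintf("<inact_model_selection> %d component(s); F = %.3g, p = %.3g\n",
              x$n_components, x$f_stat, x$p_value))
  if (x$n_components == 2L) print(x$double) else print(x$single)
  invisible(x)
}
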