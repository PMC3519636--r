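# Independent fitting oracles: coarse grid searches with local polish,
# sharing no code with the package's Levenberg-Marquardt fitters.

# Boltzmann oracle: grid over (v50, s), amplitudes solved linearly (the
# model is linear in a1, a2 given v50 and s); optional normalized forms.
oracle_boltzmann <- function(v, g, normalized = FALSE, increasing = TRUE,
                             v50_grid = seq(min(v), max(v), by = 0.25),
                             s_grid = seq(0.5, 20, by = 0.1)) {
  best <- list(rss = Inf)
  for (v50 in v50_grid) {
    for (s in s_grid) {
      occ <- 1 / (1 + exp((v - v50) / s))  # decreasing basis
      if (normalized) {
        if (increasing) {
          pred <- 1 - occ
          rss <- sum((g - pred)^2)
          pars <- c(a1 = 0, a2 = 1)
        } else {
          # g = ped + (1 - ped) * occ  ->  linear in ped given occ
          ped <- sum((g - occ) * (1 - occ)) / sum((1 - occ)^2)
          ped <- min(max(ped, 0), 1)
          rss <- sum((g - (ped + (1 - ped) * occ))^2)
          pars <- c(a1 = 1, a2 = ped)
        }
      } else {
        X <- cbind(occ, 1 - occ)  # g = a1*occ + a2*(1-occ)
        cf <- stats::lm.fit(X, g)$coefficients
        rss <- sum((g - X %*% cf)^2)
        pars <- c(a1 = cf[[1]], a2 = cf[[2]])
      }
      if (rss < best$rss) best <- list(rss = rss, v50 = v50, s = s,
                                       a1 = pars[["a1"]], a2 = pars[["a2"]])
    }
  }
  # polish v50 and s by coordinate-wise golden-section around the grid optimum
  rss_at <- function(v50, s) {
    occ <- 1 / (1 + exp((v - v50) / s))
    if (normalized && increasing) return(sum((g - (1 - occ))^2))
    if (normalized) {
      ped <- min(max(sum((g - occ) * (1 - occ)) / sum((1 - occ)^2), 0), 1)
      return(sum((g - (ped + (1 - ped) * occ))^2))
    }
    X <- cbind(occ, 1 - occ)
    cf <- stats::lm.fit(X, g)$coefficients
    sum((g - X %*% cf)^2)
  }
  for (rep in 1:3) {
    best$v50 <- stats::optimize(function(x) rss_at(x, best$s),
                                best$v50 + c(-0.5, 0.5))$minimum
    best$s <- stats::optimize(function(x) rss_at(best$v50, x),
                              pmax(best$s + c(-0.25, 0.25), 1e-3))$minimum
  }
  best$rss <- rss_at(best$v50, best$s)
  best
}

# Exponential oracle: grid over tau; offset and amplitude solved linearly.
oracle_exponential <- function(t, i, tau_grid = NULL) {
  tr <- t - t[[1]]
  if (is.null(tau_grid)) {
    tau_grid <- exp(seq(log(max(diff(t)[1], 1e-3)), log(max(tr) * 3), length.out = 400))
  }
  rss_at <- function(tau) {
    X <- cbind(1, exp(-tr / tau))
    cf <- stats::lm.fit(X, i)$coefficients
    list(rss = sum((i - X %*% cf)^2), i_i = cf[[1]], a = cf[[2]])
  }
  rss <- vapply(tau_grid, function(tau) rss_at(tau)$rss, numeric(1))
  k <- which.min(rss)
  lo <- tau_grid[max(1, k - 1)]; hi <- tau_grid[min(length(tau_grid), k + 1)]
  tau <- stats::optimize(function(tau) rss_at(tau)$rss, c(lo, hi))$minimum
  out <- rss_at(tau)
  list(tau = tau, i_i = out$i_i, a = out$a, rss = out$rss)
}

# Noiseless single-step trace generators used across tests.
make_decay <- function(tau, a = 5, i_i = 0, t_max = 10 * tau, dt = tau / 50) {
  t <- seq(0, t_max, by = dt)
  list(t = t, i = i_i + a * exp(-t / tau))
}
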