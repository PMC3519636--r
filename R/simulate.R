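#' Recording-artifact parameters
#'
#' Linear leak, capacitive transients at epoch boundaries and additive
#' Gaussian noise. With all defaults the simulation is artifact-free.
#'
#' @param g_leak Linear leak conductance, microsiemens.
#' @param e_leak Leak reversal potential, mV.
#' @param c_mem Capacitive transient scale, nF; each epoch boundary with a
#'   voltage step dV injects a spike `c_mem * dV / tau_cap * exp(-t/tau_cap)`.
#' @param noise_sd Additive Gaussian noise standard deviation, nA (0 =
#'   noiseless).
#' @param seed Integer seed for the noise generator; identical seeds give
#'   bit-identical recordings.
#' @param tau_cap Capacitive settling time constant, ms.
#' @return An `artifact_params` object.
#' @export
artifact_params <- function(g_leak = 0, e_leak = 0, c_mem = 0, noise_sd = 0,
                            seed = 1L, tau_cap = 0.1) {
  if (g_leak < 0) abort("`g_leak` must be >= 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(list(g_leak = g_leak, e_leak = e_leak, c_mem = c_mem,
                 noise_sd = noise_sd, seed = as.integer(seed), tau_cap = tau_cap),
            class = "artifact_params")
}

#' Artifact presets for excised-patch and whole-cell recordings
#'
#' Excised patches carry small leak and noise; whole-cell two-electrode
#' recordings have larger leak (kept under the ~50 nA scale typical of a
#' well-clamped oocyte), larger capacitance and more noise.
#' @param seed Integer noise seed.
#' @return An [artifact_params()].
#' @export
patch_artifacts <- function(seed = 1L) {
  artifact_params(g_leak = 0.05, e_leak = 0, c_mem = 0.02, noise_sd = 0.05, seed = seed)
}

#' @rdname patch_artifacts
#' @export
tev_artifacts <- function(seed = 1L) {
  artifact_params(g_leak = 0.25, e_leak = 0, c_mem = 0.2, noise_sd = 1, seed = seed)
}

# Gate time constant for an epoch: activation kinetics on depolarization,
# deactivation kinetics on repolarization (ties resolved as deactivation).
.tau_gate <- function(model, v, v_prev) {
  if (v > v_prev) tau_activation_at(model$activation, v)
  else tau_deactivation_at(model$deactivation, v)
}

# Simulate the gating state and ionic current of a single gating_params
# model. Returns list(currents, gating) where gating = Po*h per sample.
.sim_ionic <- function(model, protocol, solutions, mode) {
  e_k <- nernst_potential(solutions)
  time <- protocol_times(protocol)
  n_t <- length(time)
  comps <- effective_inactivation(model)
  n_c <- length(comps)
  fr <- vapply(comps, `[[`, numeric(1), "fraction")
  pedestal <- 1 - sum(fr)
  mech <- mode == "mechanistic"
  n_gates <- model$activation$n_gates

  currents <- matrix(0, protocol$n_sweeps, n_t)
  gating <- matrix(0, protocol$n_sweeps, n_t)
  bounds <- cumsum(protocol$epochs$duration)
  starts <- c(0, head(bounds, -1))

  for (sw in seq_len(protocol$n_sweeps)) {
    v_ep <- epoch_voltages(protocol, sw)
    # equilibrium at holding
    g0 <- if (mech) gate_steady_state(model$activation, protocol$holding)
          else steady_state_activation(model$activation, protocol$holding)
    h0 <- vapply(comps, function(cmp) 1 / (1 + exp((protocol$holding - cmp$v50) / cmp$s)),
                 numeric(1))
    v_prev <- protocol$holding
    for (e in seq_along(v_ep)) {
      v <- v_ep[[e]]
      idx <- which(time >= starts[[e]] - 1e-9 & time < bounds[[e]] - 1e-9)
      tr <- time[idx] - starts[[e]]
      g_inf <- if (mech) gate_steady_state(model$activation, v)
               else steady_state_activation(model$activation, v)
      if (mode == "instantaneous_activation") {
        g_t <- rep(g_inf, length(tr))
        g_end <- g_inf
      } else {
        tau_m <- .tau_gate(model, v, v_prev)
        g_t <- g_inf + (g0 - g_inf) * exp(-tr / tau_m)
        g_end <- g_inf + (g0 - g_inf) * exp(-protocol$epochs$duration[[e]] / tau_m)
      }
      po_t <- if (mech) g_t^n_gates else g_t
      h_tot <- rep(1, length(tr))
      if (n_c) {
        h_tot <- rep(pedestal, length(tr))
        for (j in seq_len(n_c)) {
          cmp <- comps[[j]]
          h_inf <- 1 / (1 + exp((v - cmp$v50) / cmp$s))
          tau_h <- tau_availability_at(cmp, v, solutions$k_out)
          h_tot <- h_tot + fr[[j]] * (h_inf + (h0[[j]] - h_inf) * exp(-tr / tau_h))
          h0[[j]] <- h_inf + (h0[[j]] - h_inf) *
            exp(-protocol$epochs$duration[[e]] / tau_h)
        }
      }
      gating[sw, idx] <- po_t * h_tot
      currents[sw, idx] <- model$g_max * po_t * h_tot * (v - e_k)
      g0 <- g_end
      v_prev <- v
    }
  }
  list(currents = currents, gating = gating)
}

# Leak + capacitive artifact currents for every sweep (noise handled by caller).
.sim_artifact_currents <- function(protocol, artifacts) {
  time <- protocol_times(protocol)
  n_t <- length(time)
  out <- matrix(0, protocol$n_sweeps, n_t)
  bounds <- cumsum(protocol$epochs$duration)
  starts <- c(0, head(bounds, -1))
  for (sw in seq_len(protocol$n_sweeps)) {
    v_ep <- epoch_voltages(protocol, sw)
    row <- numeric(n_t)
    v_prev <- protocol$holding
    for (e in seq_along(v_ep)) {
      idx <- which(time >= starts[[e]] - 1e-9 & time < bounds[[e]] - 1e-9)
      row[idx] <- row[idx] + artifacts$g_leak * (v_ep[[e]] - artifacts$e_leak)
      dv <- v_ep[[e]] - v_prev
      if (artifacts$c_mem > 0 && abs(dv) > 0 && starts[[e]] > 0) {
        after <- which(time >= starts[[e]] - 1e-9)
        row[after] <- row[after] + artifacts$c_mem * dv / artifacts$tau_cap *
          exp(-(time[after] - starts[[e]]) / artifacts$tau_cap)
      }
      v_prev <- v_ep[[e]]
    }
    out[sw, ] <- row
  }
  out
}

#' Simulate an episodic voltage-clamp recording
#'
#' Integrates a gating model through a voltage protocol and returns the
#' current sweeps, optionally with linear leak, capacitive transients and
#' additive noise. Ionic current is `g_max * Po(t) * h(t) * (V - E_K)`; a
#' [heteromer_mix()] contributes `(1 - f) * I_homomer + f * I_heteromer`.
#'
#' Three simulation modes are available. In `macroscopic` mode the open
#' probability relaxes mono-exponentially toward its Boltzmann steady state
#' (activation kinetics on depolarization, voltage-dependent deactivation
#' kinetics on repolarization), so fitted Boltzmann/exponential parameters
#' recover the configured ones. `mechanistic` mode raises a per-gate state
#' variable to the `n_gates` power, producing the sigmoidal activation delay
#' of multiple closed-closed transitions. `instantaneous_activation` clamps
#' open probability to its steady state, isolating inactivation kinetics.
#'
#' @param model A [gating_params()] or [heteromer_mix()].
#' @param protocol A [voltage_protocol()] (see [build_protocol()]).
#' @param solutions A [solution_pair()].
#' @param artifacts An [artifact_params()].
#' @param mode `"macroscopic"`, `"mechanistic"` or
#'   `"instantaneous_activation"`.
#' @param keep_state If `TRUE`, the open-probability-times-availability
#'   matrix is stored in the result (`$gating`).
#' @return A `sweep_recording`: list with `time` (ms), `currents`
#'   (n_sweeps x n_samples matrix, nA), `protocol`, `solutions` and
#'   `provenance` (model, mode, artifact settings, seed).
#' @examples
#' rec <- simulate_sweeps(kv_fixture("NvShak2"), build_protocol("activation_family"))
#' dim(rec$currents)
#' @export
simulate_sweeps <- function(model, protocol, solutions = standard_solutions(),
                            artifacts = artifact_params(),
                            mode = c("macroscopic", "mechanistic",
                                     "instantaneous_activation"),
                            keep_state = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(protocol, "voltage_protocol"),
            inherits(solutions, "solution_pair"),
            inherits(artifacts, "artifact_params"))
  .check_sampling(model, protocol, solutions)

  if (inherits(model, "heteromer_mix")) {
    hom <- .sim_ionic(model$homomer, protocol, solutions, mode)
    het <- .sim_ionic(model$heteromer, protocol, solutions, mode)
    f <- model$het_fraction
    ionic <- list(
      currents = (1 - f) * hom$currents + f * het$currents,
      gating = (1 - f) * hom$gating + f * het$gating
    )
    model_name <- sprintf("%s+%s(f=%g)", model$homomer$name, model$heteromer$name, f)
  } else if (inherits(model, "gating_params")) {
    ionic <- .sim_ionic(model, protocol, solutions, mode)
    model_name <- model$name
  } else {
    abort("`model` must be a gating_params or heteromer_mix object.")
  }

  currents <- ionic$currents + .sim_artifact_currents(protocol, artifacts)
  if (artifacts$noise_sd > 0) {
    currents <- currents + .with_local_seed(artifacts$seed, {
      matrix(stats::rnorm(length(currents), 0, artifacts$noise_sd),
             nrow = nrow(currents))
    })
  }

  rec <- structure(
    list(time = protocol_times(protocol), currents = currents,
         protocol = protocol, solutions = solutions,
         provenance = list(model = model, model_name = model_name, mode = mode,
                           artifacts = artifacts, seed = artifacts$seed,
                           leak_subtracted = FALSE)),
    class = "sweep_recording"
  )
  if (keep_state) rec$gating <- ionic$gating
  rec
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Warn when dt undersamples the fastest relaxation in play.
.check_sampling <- function(model, protocol, solutions) {
  models <- if (inherits(model, "heteromer_mix")) list(model$homomer, model$heteromer)
            else list(model)
  tau_min <- Inf
  for (m in models) {
    if (!inherits(m, "gating_params")) next
    v_all <- unique(unlist(lapply(seq_len(protocol$n_sweeps), epoch_voltages,
                                  protocol = protocol)))
    tau_min <- min(tau_min,
                   tau_activation_at(m$activation, max(v_all)),
                   tau_deactivation_at(m$deactivation, min(v_all)))
    for (cmp in effective_inactivation(m)) {
      tau_min <- min(tau_min, cmp$tau_inact)
    }
  }
  if (protocol$dt > tau_min / 5) {
    warn(sprintf(
      "Sampling interval dt = %g ms is coarse relative to the fastest time constant (%.3g ms); consider dt <= %.3g ms.",
      protocol$dt, tau_min, tau_min / 5))
  }
  invisible(tau_min)
}

#' @export
print.sweep_recording <- function(x, ...) {
  cat(sprintf("<sweep_recording> %s | %s | %d sweeps x %d samples (dt %g ms)%s\n",
              x$provenance$model_name, x$protocol$name, nrow(x$currents),
              ncol(x$currents), x$protocol$dt,
              if (isTRUE(x$provenance$leak_subtracted)) " [leak-subtracted]" else ""))
  invisible(x)
}

#' Long-format view of a recording
#'
#' @param x A `sweep_recording`.
#' @param ... Unused.
#' @return A tibble with columns `sweep`, `time_ms`, `voltage_mV`,
#'   `current_nA`.
#' @export
as_tibble.sweep_recording <- function(x, ...) {
  n_sw <- nrow(x$currents)
  purrr::map_dfr(seq_len(n_sw), function(sw) {
    tibble::tibble(
      sweep = sw,
      time_ms = x$time,
      voltage_mV = voltage_trace(x$protocol, sw),
      current_nA = x$currents[sw, ]
    )
  })
}

#' P/N leak subtraction
#'
#' Estimates the linear leak and capacitive response from `n_sub` scaled
#' sub-sweeps delivered from a hyperpolarized sub-holding potential (P/-N:
#' each sub-pulse is the main-pulse deviation scaled by `-1/n_sub`, so
#' channels stay closed) and removes it from the main recording, along with
#' the holding-level baseline. Any strictly linear component is removed
#' exactly; nonlinear (channel) current is preserved.
#'
#' The sub-sweeps are regenerated from the recording's provenance (same
#' model, artifact settings and mode), mirroring an acquisition system that
#' interleaves sub-pulses with each sweep.
#'
#' @param main A `sweep_recording` produced by [simulate_sweeps()].
#' @param n_sub Number of sub-pulses (>= 1).
#' @param sub_hold Sub-pulse holding potential, mV.
#' @return A leak-subtracted `sweep_recording`.
#' @export
pn_leak_subtract <- function(main, n_sub = 4L, sub_hold = -100) {
  stopifnot(inherits(main, "sweep_recording"))
  if (n_sub < 1) abort("`n_sub` must be >= 1.")
  prov <- main$provenance
  protocol <- main$protocol

  sub_epochs <- protocol$epochs
  sub_epochs$v_start <- sub_hold - (sub_epochs$v_start - protocol$holding) / n_sub
  sub_epochs$v_inc <- -sub_epochs$v_inc / n_sub
  sub_protocol <- voltage_protocol(paste0(protocol$name, "_pn_sub"), protocol$dt,
                                   sub_epochs, protocol$n_sweeps, sub_hold)

  sub_sum <- 0
  for (k in seq_len(n_sub)) {
    art_k <- prov$artifacts
    art_k$seed <- prov$artifacts$seed + k
    sub_k <- suppressWarnings(simulate_sweeps(
      prov$model, sub_protocol, main$solutions, art_k, mode = prov$mode))
    sub_sum <- sub_sum + sub_k$currents
  }
  sub_mean <- sub_sum / n_sub

  # Baseline (holding-level) estimates from the initial constant epoch.
  first_dur <- protocol$epochs$duration[[1]]
  base_idx <- which(main$time < first_dur - 1e-9)
  b_sub <- rowMeans(sub_mean[, base_idx, drop = FALSE])
  b_main <- rowMeans(main$currents[, base_idx, drop = FALSE])

  .check_sub_linearity(sub_mean, sub_protocol, b_sub)

  # linear response to the main deviation is -n_sub * (sub_mean - b_sub)
  corrected <- main$currents - b_main + n_sub * (sub_mean - b_sub)

  out <- main
  out$currents <- corrected
  out$provenance$leak_subtracted <- TRUE
  out$provenance$pn <- list(n_sub = n_sub, sub_hold = sub_hold)
  out
}

# Warn if sub-sweep currents deviate from linearity in V (channels opening).
# Steady-state current (last 20% of each epoch, past capacitive settling) is
# pooled across all epochs and sweeps and regressed on voltage.
.check_sub_linearity <- function(sub_mean, sub_protocol, b_sub) {
  time <- protocol_times(sub_protocol)
  bounds <- cumsum(sub_protocol$epochs$duration)
  starts <- c(0, head(bounds, -1))
  v_pts <- numeric(0); i_pts <- numeric(0)
  for (sw in seq_len(nrow(sub_mean))) {
    v_ep <- epoch_voltages(sub_protocol, sw)
    for (e in seq_along(v_ep)) {
      idx <- which(time >= starts[[e]] + 0.8 * sub_protocol$epochs$duration[[e]] &
                     time < bounds[[e]] - 1e-9)
      if (length(idx) < 2) next
      v_pts <- c(v_pts, v_ep[[e]])
      i_pts <- c(i_pts, mean(sub_mean[sw, idx]))
    }
  }
  if (length(unique(v_pts)) < 3) return(invisible(TRUE))
  fit <- stats::lm.fit(cbind(1, v_pts), i_pts)
  scale <- max(abs(i_pts - mean(i_pts)), 1e-9)
  if (max(abs(fit$residuals)) > 0.02 * scale + 1e-9) {
    warn("P/N sub-sweeps deviate from linearity; channels may be activating in the sub-pulse range.")
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
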