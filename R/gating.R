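#' Voltage-activation parameters
#'
#' Phenomenological description of activation gating: the steady-state open
#' probability follows a Boltzmann function of voltage, and relaxation toward
#' it is exponential with a voltage-dependent time constant.
#'
#' @param v50 Half-activation voltage of the steady-state open probability, mV.
#' @param s Boltzmann slope factor, mV (> 0; smaller is steeper).
#' @param n_gates Number of independent activation gates (integer >= 1). In
#'   mechanistic simulation mode open probability is `m^n_gates`, which
#'   produces the sigmoidal delay characteristic of multiple closed-closed
#'   transitions; macroscopic mode ignores it.
#' @param tau_act_ref Activation time constant at the +60 mV reference
#'   voltage, ms.
#' @param tau_act_vslope e-fold voltage dependence of the activation time
#'   constant, mV (tau shrinks e-fold per `tau_act_vslope` of depolarization).
#'
#' @return An `activation_params` object.
#' @export
activation_params <- function(v50, s, n_gates = 4L, tau_act_ref = 1, tau_act_vslope = 80) {
  if (s <= 0) abort("Activation slope `s` must be > 0 mV.")
  if (n_gates < 1 || n_gates != round(n_gates)) abort("`n_gates` must be an integer >= 1.")
  if (tau_act_ref <= 0) abort("`tau_act_ref` must be > 0 ms.")
  structure(
    list(v50 = v50, s = s, n_gates = as.integer(n_gates),
         tau_act_ref = tau_act_ref, tau_act_vslope = tau_act_vslope),
    class = "activation_params"
  )
}

#' Deactivation (channel closing) parameters
#'
#' Tail-current decay is exponential with a time constant that depends
#' e-fold-per-`tau_deact_vslope` on voltage, i.e. log(tau) is linear in V
#' (the semi-logarithmic relation used to quantify closing-transition voltage
#' dependence).
#'
#' @param tau_deact_ref Deactivation time constant at the -100 mV reference
#'   voltage, ms.
#' @param tau_deact_vslope e-fold voltage dependence, mV.
#' @return A `deactivation_params` object.
#' @export
deactivation_params <- function(tau_deact_ref = 5, tau_deact_vslope = 40) {
  if (tau_deact_ref <= 0) abort("`tau_deact_ref` must be > 0 ms.")
  structure(list(tau_deact_ref = tau_deact_ref, tau_deact_vslope = tau_deact_vslope),
            class = "deactivation_params")
}

#' One inactivation component
#'
#' A channel may carry several inactivation components (e.g. a fast N-type
#' ball-and-chain component plus a slower C-type pore-collapse component).
#' Each component contributes a fractional amplitude to the availability
#' variable; fractions across components must sum to <= 1, any remainder
#' being a non-inactivating pedestal.
#'
#' @param mechanism `"N_type"` (removed by N-terminal truncation),
#'   `"C_type"` (suppressed by high external K+), or `"intrinsic"`
#'   (mechanism-agnostic: removed by neither; used for channels whose partial
#'   inactivation responds to neither manipulation).
#' @param tau_inact Inactivation time constant at +60 mV under the standard
#'   2 mM external K+ condition, ms.
#' @param fraction Fractional amplitude in (0, 1].
#' @param v50,s Half-voltage (mV) and slope (mV, > 0) of this component's
#'   steady-state inactivation Boltzmann.
#' @param tau_recovery Recovery time constant governing availability kinetics
#'   at voltages below 0 mV, ms.
#' @param k_half_external C-type only: external K+ concentration (mM) at
#'   which the C-type rate is halved relative to its zero-K+ limit.
#' @return An `inact_component` object.
#' @export
inact_component <- function(mechanism = c("N_type", "C_type", "intrinsic"),
                            tau_inact, fraction = 1, v50, s,
                            tau_recovery = 100, k_half_external = 5) {
  mechanism <- match.arg(mechanism)
  if (tau_inact <= 0) abort("`tau_inact` must be > 0 ms.")
  if (tau_recovery <= 0) abort("`tau_recovery` must be > 0 ms.")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must lie in (0, 1].")
  if (s <= 0) abort("Inactivation slope `s` must be > 0 mV.")
  structure(
    list(mechanism = mechanism, tau_inact = tau_inact, fraction = fraction,
         v50 = v50, s = s, tau_recovery = tau_recovery,
         k_half_external = k_half_external),
    class = "inact_component"
  )
}

#' Full gating-parameter set for one channel species
#'
#' @param name Channel label.
#' @param g_max Maximal conductance, microsiemens.
#' @param activation An [activation_params()].
#' @param deactivation A [deactivation_params()].
#' @param inactivation List of [inact_component()]s (possibly empty).
#'   Fractions must sum to <= 1.
#' @param truncated If `TRUE`, models an N-terminally truncated construct:
#'   all N-type components are removed; C-type and intrinsic components are
#'   untouched.
#' @return A `gating_params` object.
#' @export
gating_params <- function(name, g_max = 1, activation, deactivation = deactivation_params(),
                          inactivation = list(), truncated = FALSE) {
  stopifnot(inherits(activation, "activation_params"),
            inherits(deactivation, "deactivation_params"))
  if (g_max <= 0) abort("`g_max` must be > 0 uS.")
  if (length(inactivation)) {
    ok <- vapply(inactivation, inherits, logical(1), "inact_component")
    if (!all(ok)) abort("`inactivation` must be a list of inact_component objects.")
    fsum <- sum(vapply(inactivation, `[[`, numeric(1), "fraction"))
    if (fsum > 1 + 1e-9) {
      abort(sprintf("Inactivation fractions sum to %.3f; must be <= 1.", fsum))
    }
  }
  structure(
    list(name = name, g_max = g_max, activation = activation,
         deactivation = deactivation, inactivation = inactivation,
         truncated = isTRUE(truncated)),
    class = "gating_params"
  )
}

#' @export
print.gating_params <- function(x, ...) {
  inact <- effective_inactivation(x)
  cat(sprintf("<gating_params> %s%s: g_max %g uS, GV V50 %.1f mV (s %.1f), %d inactivation component(s)\n",
              x$name, if (x$truncated) " [truncated]" else "",
              x$g_max, x$activation$v50, x$activation$s, length(inact)))
  invisible(x)
}

#' Mixture of homomeric and heteromeric channels
#'
#' Co-expression of a homotetramer-competent subunit with a regulatory
#' subunit yields a mixed population; the recorded current is the weighted
#' sum of a pure homomeric and a pure heteromeric component.
#'
#' @param homomer,heteromer [gating_params()] for the two populations.
#' @param het_fraction Fraction of maximal conductance carried by heteromeric
#'   channels, in `[0, 1]`.
#' @return A `heteromer_mix` object.
#' @export
heteromer_mix <- function(homomer, heteromer, het_fraction = 0.5) {
  stopifnot(inherits(homomer, "gating_params"), inherits(heteromer, "gating_params"))
  if (het_fraction < 0 || het_fraction > 1) abort("`het_fraction` must lie in [0, 1].")
  structure(list(homomer = homomer, heteromer = heteromer, het_fraction = het_fraction),
            class = "heteromer_mix")
}

#' Effective inactivation components of a construct
#'
#' Applies the truncation rule: a truncated construct loses every N-type
#' component while C-type and intrinsic components persist.
#'
#' @param model A [gating_params()].
#' @return A list of [inact_component()]s.
#' @export
effective_inactivation <- function(model) {
  stopifnot(inherits(model, "gating_params"))
  comps <- model$inactivation
  if (model$truncated) {
    comps <- purrr::discard(comps, ~ .x$mechanism == "N_type")
  }
  comps
}

#' Steady-state activation (open probability at equilibrium)
#'
#' The Boltzmann relation `1 / (1 + exp(-(v - v50) / s))`: strictly
#' increasing in voltage, 0.5 at `v50`.
#'
#' @param params An [activation_params()] or [gating_params()].
#' @param v Voltage(s), mV.
#' @return Open-probability fraction(s) in (0, 1).
#' @export
steady_state_activation <- function(params, v) {
  if (inherits(params, "gating_params")) params <- params$activation
  stopifnot(inherits(params, "activation_params"))
  1 / (1 + exp(-(v - params$v50) / params$s))
}

#' Steady-state availability (fraction not inactivated at equilibrium)
#'
#' `pedestal + sum_j fraction_j / (1 + exp((v - v50_j) / s_j))` where the
#' pedestal is `1 - sum(fraction_j)`. Non-increasing in voltage; tends to 1
#' as v -> -Inf.
#'
#' @param components List of [inact_component()]s, or a [gating_params()]
#'   (whose effective components after truncation are used).
#' @param v Voltage(s), mV.
#' @return Availability fraction(s) in (0, 1].
#' @export
steady_state_availability <- function(components, v) {
  if (inherits(components, "gating_params")) {
    components <- effective_inactivation(components)
  }
  if (!length(components)) return(rep(1, length(v)))
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  if (sum(fr) > 1 + 1e-9) abort("Inactivation fractions sum to > 1: invalid model.")
  ped <- 1 - sum(fr)
  out <- rep(ped, length(v))
  for (comp in components) {
    out <- out + comp$fraction / (1 + exp((v - comp$v50) / comp$s))
  }
  out
}

# Voltage-dependent activation time constant (ms): e-fold faster per
# tau_act_vslope mV of depolarization, referenced to +60 mV.
tau_activation_at <- function(activation, v) {
  activation$tau_act_ref * exp((60 - v) / activation$tau_act_vslope)
}

# Voltage-dependent deactivation time constant (ms), referenced to -100 mV.
tau_deactivation_at <- function(deactivation, v) {
  deactivation$tau_deact_ref * exp((v + 100) / deactivation$tau_deact_vslope)
}

# External-K+ scaling of the C-type rate: proportional to
# k_half / (k_half + k_out), normalized to 1 at the 2 mM reference condition
# so configured time constants are realized under standard solutions.
ctype_rate_scale <- function(k_half, k_out) {
  (k_half + .K_OUT_REF) / (k_half + k_out)
}

# Effective availability relaxation time constant for one component at
# voltage v and external K+ k_out (ms). Development kinetics (tau_inact)
# apply at and above 0 mV; recovery kinetics below.
tau_availability_at <- function(comp, v, k_out) {
  tau <- ifelse(v >= 0, comp$tau_inact, comp$tau_recovery)
  if (comp$mechanism == "C_type") {
    tau <- tau / ctype_rate_scale(comp$k_half_external, k_out)
  }
  tau
}

#' Forward/backward transition rates implied by the phenomenological model
#'
#' Expands the time-constant/steady-state description into per-gate
#' activation rates (alpha, beta with `alpha + beta = 1/tau`,
#' `m_inf = alpha * tau`) and per-component inactivation/recovery rates.
#' C-type inactivation rates scale with external K+ as
#' `k_half / (k_half + k_out)` (normalized to the standard 2 mM condition);
#' N-type and intrinsic rates are K+-independent.
#'
#' @param model A [gating_params()].
#' @param v Voltage, mV (scalar).
#' @param k_out External K+ concentration, mM.
#' @param direction `"depolarization"` (activation kinetics) or
#'   `"repolarization"` (deactivation kinetics) for the gate time constant.
#' @return A tibble with one row per rate: `process`, `component`, `rate_fwd`
#'   (1/ms), `rate_back` (1/ms), `tau` (ms), `steady_state`.
#' @export
kinetic_rates <- function(model, v, k_out = 2,
                          direction = c("depolarization", "repolarization")) {
  stopifnot(inherits(model, "gating_params"), length(v) == 1L)
  direction <- match.arg(direction)
  tau_m <- if (direction == "depolarization") {
    tau_activation_at(model$activation, v)
  } else {
    tau_deactivation_at(model$deactivation, v)
  }
  m_inf <- gate_steady_state(model$activation, v)
  rows <- list(tibble::tibble(
    process = "activation_gate", component = NA_character_,
    rate_fwd = m_inf / tau_m, rate_back = (1 - m_inf) / tau_m,
    tau = tau_m, steady_state = m_inf
  ))
  comps <- effective_inactivation(model)
  for (i in seq_along(comps)) {
    comp <- comps[[i]]
    tau_h <- tau_availability_at(comp, v, k_out)
    h_inf <- 1 / (1 + exp((v - comp$v50) / comp$s))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      process = "inactivation", component = paste0(comp$mechanism, "_", i),
      rate_fwd = (1 - h_inf) / tau_h, rate_back = h_inf / tau_h,
      tau = tau_h, steady_state = h_inf
    )
  }
  dplyr::bind_rows(rows)
}

# Per-gate steady state for mechanistic mode: a Boltzmann shifted so that
# m_inf^n crosses 0.5 exactly at the configured macroscopic v50.
gate_steady_state <- function(activation, v) {
  n <- activation$n_gates
  v50_gate <- activation$v50 + activation$s * log(2^(1 / n) - 1)
  1 / (1 + exp(-(v - v50_gate) / activation$s))
}
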