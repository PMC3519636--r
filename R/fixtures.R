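# Registry of channel parameter sets.
#
# The six NvShak homotetramer entries carry the published voltage-dependent
# parameters (GV and SSI Boltzmann midpoints/slopes and inactivation time
# constants) verbatim; those fields are acceptance-grade. Kinetic time
# constants for activation and deactivation are not published numerically
# and are encoded here only by their qualitative rank order (NvShak5 fastest
# / NvShak1 slowest activation; NvShak6 fastest / NvShak1 slowest
# deactivation, ~10-fold span); they are illustrative, as is the whole
# "Kv1.2like" reference entry.
.fixture_registry <- function() {
  list(
    NvShak1 = list(
      authority = "acceptance",
      provenance = "published summary table, row 1",
      model = gating_params(
        "NvShak1", g_max = 1,
        activation = activation_params(v50 = -19.5, s = 5.7, n_gates = 4L,
                                       tau_act_ref = 3.5, tau_act_vslope = 80),
        deactivation = deactivation_params(tau_deact_ref = 12, tau_deact_vslope = 40),
        inactivation = list(
          inact_component("N_type", tau_inact = 2.4, fraction = 1,
                          v50 = -20.3, s = 3.3, tau_recovery = 100)
        )
      )
    ),
    NvShak2 = list(
      authority = "acceptance",
      provenance = "published summary table, row 2 (high-threshold, non-inactivating)",
      model = gating_params(
        "NvShak2", g_max = 1,
        activation = activation_params(v50 = 2.1, s = 3.3, n_gates = 4L,
                                       tau_act_ref = 1.4, tau_act_vslope = 80),
        deactivation = deactivation_params(tau_deact_ref = 6, tau_deact_vslope = 40)
      )
    ),
    NvShak3 = list(
      authority = "acceptance",
      provenance = "published summary table, row 3 (high-threshold, non-inactivating)",
      model = gating_params(
        "NvShak3", g_max = 1,
        activation = activation_params(v50 = -0.8, s = 3.6, n_gates = 4L,
                                       tau_act_ref = 1.4, tau_act_vslope = 80),
        deactivation = deactivation_params(tau_deact_ref = 6, tau_deact_vslope = 40)
      )
    ),
    NvShak4 = list(
      authority = "acceptance",
      provenance = "published summary table, row 4 (double-exponential inactivation; slow component is the K+-sensitive C-type process unmasked by truncation)",
      model = gating_params(
        "NvShak4", g_max = 1,
        activation = activation_params(v50 = -27.4, s = 2.2, n_gates = 4L,
                                       tau_act_ref = 0.9, tau_act_vslope = 80),
        deactivation = deactivation_params(tau_deact_ref = 4, tau_deact_vslope = 40),
        inactivation = list(
          inact_component("N_type", tau_inact = 33.5, fraction = 0.32,
                          v50 = -37.0, s = 2.2, tau_recovery = 100),
          inact_component("C_type", tau_inact = 153.6, fraction = 0.68,
                          v50 = -37.0, s = 2.2, tau_recovery = 100,
                          k_half_external = 5)
        )
      )
    ),
    NvShak5 = list(
      authority = "acceptance",
      provenance = "published summary table, row 5",
      model = gating_params(
        "NvShak5", g_max = 1,
        activation = activation_params(v50 = -30.1, s = 4.3, n_gates = 4L,
                                       tau_act_ref = 0.7, tau_act_vslope = 80),
        deactivation = deactivation_params(tau_deact_ref = 2.5, tau_deact_vslope = 40),
        inactivation = list(
          inact_component("N_type", tau_inact = 14.1, fraction = 1,
                          v50 = -59.0, s = 6.1, tau_recovery = 100)
        )
      )
    ),
    NvShak6 = list(
      authority = "acceptance",
      provenance = "published summary table, row 6 (partial inactivation removed by neither truncation nor K+; modelled mechanism-agnostic, fraction/time constants illustrative)",
      model = gating_params(
        "NvShak6", g_max = 1,
        activation = activation_params(v50 = -25.7, s = 3.6, n_gates = 4L,
                                       tau_act_ref = 1.0, tau_act_vslope = 80),
        deactivation = deactivation_params(tau_deact_ref = 1.2, tau_deact_vslope = 40),
        inactivation = list(
          inact_component("intrinsic", tau_inact = 150, fraction = 0.6,
                          v50 = -46.2, s = 3.1, tau_recovery = 150)
        )
      )
    ),
    Kv1.2like = list(
      authority = "illustrative",
      provenance = "synthetic bilaterian Shaker reference; all values illustrative, not from any publication",
      model = gating_params(
        "Kv1.2like", g_max = 1,
        activation = activation_params(v50 = -25, s = 6, n_gates = 4L,
                                       tau_act_ref = 0.8, tau_act_vslope = 80),
        deactivation = deactivation_params(tau_deact_ref = 1.3, tau_deact_vslope = 40)
      )
    )
  )
}

#' List the registered channel fixtures
#'
#' @return A tibble with one row per registered homotetramer parameter set:
#'   `name`, `authority` (`"acceptance"` entries carry published Boltzmann /
#'   time-constant values verbatim; `"illustrative"` entries are synthetic),
#'   `provenance`, and the headline gating parameters.
#' @export
kv_fixtures <- function() {
  reg <- .fixture_registry()
  purrr::map_dfr(names(reg), function(nm) {
    m <- reg[[nm]]$model
    comps <- m$inactivation
    tibble::tibble(
      name = nm,
      authority = reg[[nm]]$authority,
      gv_v50 = m$activation$v50,
      gv_slope = m$activation$s,
      n_inact_components = length(comps),
      ssi_v50 = if (length(comps)) comps[[1]]$v50 else NA_real_,
      ssi_slope = if (length(comps)) comps[[1]]$s else NA_real_,
      tau_inact = paste(vapply(comps, function(cp)
        sprintf("%g (%g)", cp$tau_inact, cp$fraction), character(1)),
        collapse = " + "),
      provenance = reg[[nm]]$provenance
    )
  })
}

#' Load a registered channel fixture
#'
#' @param name Fixture name (see [kv_fixtures()]).
#' @param truncated If `TRUE`, return the N-terminally truncated construct
#'   (all N-type inactivation removed).
#' @param g_max Optional maximal-conductance override, microsiemens.
#' @return A [gating_params()].
#' @examples
#' kv_fixture("NvShak5")
#' kv_fixture("NvShak1", truncated = TRUE)
#' @export
kv_fixture <- function(name, truncated = FALSE, g_max = NULL) {
  reg <- .fixture_registry()
  if (!name %in% names(reg)) {
    abort(sprintf("Unknown fixture '%s'. Registered: %s.",
                  name, paste(names(reg), collapse = ", ")))
  }
  model <- reg[[name]]$model
  model$truncated <- isTRUE(truncated)
  if (!is.null(g_max)) model$g_max <- g_max
  model
}

# Heteromer co-expression presets. Table-style qualitative phenotypes are
# published; every numeric parameter below is the package's own encoding of
# those qualitative levels. The whole-cell homomeric reference uses a
# depolarized activation range (V50 +18 mV) so its first detectable step is
# +10 mV, as observed for the two-electrode controls; heteromer activation
# offsets then realize small/medium/large hyperpolarizing threshold shifts
# (10/20/30 mV of earlier first appearance) and the kinetic presets realize
# slow (>1.5x) or fast (<0.67x) activation/deactivation ratios.
.het_homomer_tev <- function() {
  gating_params(
    "NvShak3tev", g_max = 5,
    activation = activation_params(v50 = 18, s = 3.6, n_gates = 4L,
                                   tau_act_ref = 1.4, tau_act_vslope = 80),
    deactivation = deactivation_params(tau_deact_ref = 6, tau_deact_vslope = 40)
  )
}

.het_registry <- function() {
  base <- .het_homomer_tev()
  mk <- function(tag, v50 = base$activation$v50, tau_act = 1.4, tau_deact = 6,
                 inact = list()) {
    gating_params(
      paste0("NvShak3/", tag), g_max = 5,
      activation = activation_params(v50 = v50, s = 3.6, n_gates = 4L,
                                     tau_act_ref = tau_act, tau_act_vslope = 80),
      deactivation = deactivation_params(tau_deact_ref = tau_deact,
                                         tau_deact_vslope = 40),
      inactivation = inact
    )
  }
  slow_in <- function(tau, fraction = 1, v50 = -40) {
    list(inact_component("intrinsic", tau_inact = tau, fraction = fraction,
                         v50 = v50, s = 5, tau_recovery = 200))
  }
  list(
    # slowly inactivating heteromer (~1 s to complete at +60 mV)
    NvShakR1 = heteromer_mix(base, mk("R1", inact = slow_in(300)), 0.5),
    # medium threshold shift, slow activation, slow deactivation
    NvShakR2 = heteromer_mix(base, mk("R2", v50 = -5, tau_act = 4.2, tau_deact = 18), 0.6),
    # small shift, slow activation, slow deactivation
    NvShakR4 = heteromer_mix(base, mk("R4", v50 = 8, tau_act = 4.2, tau_deact = 18), 0.6),
    # large shift, fast activation, unchanged deactivation
    NvShakR5 = heteromer_mix(base, mk("R5", v50 = -15, tau_act = 0.42), 0.85),
    # medium shift, slow activation, slow deactivation
    NvShakR6 = heteromer_mix(base, mk("R6", v50 = -5, tau_act = 4.2, tau_deact = 18), 0.6),
    # slow activation only
    NvShakR7 = heteromer_mix(base, mk("R7", tau_act = 4.2), 0.6),
    # fast inactivation (incomplete), large shift, slow deactivation
    NvShakR8 = heteromer_mix(base, mk("R8", v50 = -15, tau_deact = 30,
                                      inact = list(inact_component(
                                        "intrinsic", tau_inact = 30, fraction = 0.6,
                                        v50 = -25, s = 5, tau_recovery = 200))), 0.75),
    # medium shift, slow activation, slow deactivation
    NvShakR9 = heteromer_mix(base, mk("R9", v50 = -5, tau_act = 4.2, tau_deact = 18), 0.6),
    # very fast, complete inactivation (< 50 ms at +60 mV)
    NvShakR11 = heteromer_mix(base, mk("R11", inact = slow_in(6)), 0.6),
    NvShakR12 = heteromer_mix(base, mk("R12", inact = slow_in(8)), 0.6),
    NvShakR14 = heteromer_mix(base, mk("R14", inact = slow_in(10)), 0.6)
  )
}

#' Load a regulatory-subunit heteromer preset
#'
#' Each preset is a [heteromer_mix()] of a homomeric whole-cell reference
#' channel and a heteromer carrying that regulatory subunit's qualitative
#' phenotype (novel inactivation, hyperpolarizing threshold shift, altered
#' activation/deactivation kinetics). Numeric preset parameters are the
#' package's own encoding of the published qualitative levels.
#'
#' @param name Preset name, e.g. `"NvShakR8"` (see
#'   `names(kv_heteromer_presets())`).
#' @return A [heteromer_mix()].
#' @export
kv_heteromer_preset <- function(name) {
  reg <- .het_registry()
  if (!name %in% names(reg)) {
    abort(sprintf("Unknown heteromer preset '%s'. Registered: %s.",
                  name, paste(names(reg), collapse = ", ")))
  }
  reg[[name]]
}

#' @rdname kv_heteromer_preset
#' @export
kv_heteromer_presets <- function() .het_registry()

#' Homomeric whole-cell reference channel for heteromer assays
#'
#' The two-electrode whole-cell counterpart of the high-threshold
#' non-inactivating homomer: identical kinetics, but with the activation
#' range depolarized so the first detectable current step is +10 mV, as
#' observed for whole-cell controls.
#' @return A [gating_params()].
#' @export
kv_heteromer_homomer <- function() .het_homomer_tev()
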