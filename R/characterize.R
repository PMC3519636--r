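#' Classify activation threshold from the GV midpoint
#'
#' High-threshold channels activate only at depolarized voltages (GV
#' midpoints at or above 0 mV); low-threshold channels have negative
#' midpoints. The boundary value 0 mV is classified high.
#'
#' @param gv_v50 GV Boltzmann midpoint(s), mV.
#' @return `"high"` or `"low"` (character, vectorized).
#' @export
classify_threshold <- function(gv_v50) {
  ifelse(gv_v50 >= 0, "high", "low")
}

# Inactivation phenotype from a +60 mV decay trace.
#   none:    < 5% decay from peak
#   partial: > 15% of peak remains at trace end, with real decay
#   fast:    amplitude-weighted tau < 20 ms
#   slow:    otherwise
.inactivation_class <- function(decay_frac, residual_frac, tau_weighted) {
  if (decay_frac < 0.05) return("none")
  if (residual_frac > 0.15) return("partial")
  if (tau_weighted < 20) return("fast")
  "slow"
}

# Extract the +60 mV decay (from peak to step end) of a recording whose
# varying step epoch includes +60 mV, or whose single step is at +60.
.decay_trace <- function(recording, v_target = 60, blank = 0.3) {
  protocol <- recording$protocol
  step <- tryCatch(.varying_epoch(protocol), error = function(e) NULL)
  if (is.null(step)) {
    # fixed-voltage protocols: use the largest-voltage epoch
    step <- which.max(protocol$epochs$v_start)
    sw <- 1L
  } else {
    v_steps <- protocol$epochs$v_start[[step]] +
      (seq_len(protocol$n_sweeps) - 1) * protocol$epochs$v_inc[[step]]
    sw <- which.min(abs(v_steps - v_target))
  }
  t_on <- sum(protocol$epochs$duration[seq_len(step - 1)])
  t_off <- t_on + protocol$epochs$duration[[step]]
  idx <- which(recording$time >= t_on + blank - 1e-9 & recording$time < t_off - 1e-9)
  i <- recording$currents[sw, idx]
  t <- recording$time[idx]
  pk <- which.max(abs(i))
  list(t = t[pk:length(t)], i = i[pk:length(i)])
}

#' Summarize one channel's voltage-dependent properties
#'
#' Assembles a summary-table row from a bundle of recordings: the
#' inactivation time constant(s) at +60 mV (with automatic single- vs
#' double-exponential selection), the steady-state-inactivation Boltzmann,
#' the GV Boltzmann from isochronal tails, and derived phenotype labels.
#' When a truncated-construct bundle is supplied, its `gv_tail` recordings
#' are used for the GV fit (N-type inactivation otherwise distorts the
#' activation time course), mirroring the use of N-terminally truncated
#' constructs.
#'
#' @param bundle Named list of recordings for the full-length channel:
#'   `activation_family` (a `sweep_recording`; used for the +60 mV
#'   inactivation fit), `gv_tail` and `ssi` (each a `sweep_recording` or
#'   list of per-cell recordings).
#' @param truncated_bundle Optional named list for the truncated construct;
#'   its `gv_tail` member replaces the full-length one for GV fitting.
#' @param name Channel name for the summary row (defaults to the recording
#'   provenance).
#' @return A one-row tibble: `name`, `tau_inact` (list column of tibbles
#'   with `tau`, `fraction`), `tau_label`, `ssi_v50`, `ssi_slope`, `gv_v50`,
#'   `gv_slope`, `threshold_class`, `inactivation_class`. SSI fields and
#'   `tau_inact` are `NA` for non-inactivating channels.
#' @export
summarize_channel <- function(bundle, truncated_bundle = NULL, name = NULL) {
  need <- c("activation_family", "gv_tail", "ssi")
  missing <- setdiff(need, names(bundle))
  # ssi is optional for channels known not to inactivate
  missing <- setdiff(missing, "ssi")
  if (length(missing)) {
    abort(sprintf("Bundle is missing required member(s): %s",
                  paste(missing, collapse = ", ")))
  }
  act_rec <- bundle$activation_family
  name <- name %||% act_rec$provenance$model_name

  # --- inactivation at +60 mV ---
  dec <- .decay_trace(act_rec, 60)
  peak <- abs(dec$i[[1]])
  end_val <- abs(mean(tail(dec$i, max(3, length(dec$i) %/% 50))))
  decay_frac <- (peak - end_val) / max(peak, 1e-12)
  tau_tbl <- NULL
  tau_label <- NA_character_
  tau_weighted <- Inf
  if (decay_frac >= 0.05) {
    sel <- select_inactivation_model(dec$t, dec$i)
    if (sel$n_components == 2L) {
      tau_tbl <- tibble::tibble(tau = c(sel$double$tau1, sel$double$tau2),
                                fraction = c(sel$double$f1, sel$double$f2))
      tau_label <- sprintf("%.1f (%.2f) + %.1f (%.2f)",
                           sel$double$tau1, sel$double$f1,
                           sel$double$tau2, sel$double$f2)
    } else {
      tau_tbl <- tibble::tibble(tau = sel$single$tau, fraction = 1)
      tau_label <- sprintf("%.1f", sel$single$tau)
    }
    tau_weighted <- sum(tau_tbl$tau * tau_tbl$fraction)
  }

  # --- steady-state inactivation ---
  ssi_v50 <- NA_real_; ssi_slope <- NA_real_
  ssi_curve <- NULL
  if (!is.null(bundle$ssi) && decay_frac >= 0.05) {
    ssi_curve <- build_ssi_curve(bundle$ssi)
    # a flat availability curve means no steady-state inactivation
    if (min(ssi_curve$data$mean) < 0.95) {
      ssi_v50 <- ssi_curve$v50
      ssi_slope <- ssi_curve$s
    }
  }

  # --- GV from isochronal tails ---
  gv_bundle <- if (!is.null(truncated_bundle$gv_tail)) truncated_bundle$gv_tail
               else bundle$gv_tail
  gv_curve <- build_gv_curve(gv_bundle)

  inact_class <- .inactivation_class(decay_frac, end_val / max(peak, 1e-12),
                                     tau_weighted)
  tibble::tibble(
    name = name,
    tau_inact = list(tau_tbl),
    tau_label = tau_label,
    ssi_v50 = ssi_v50,
    ssi_slope = ssi_slope,
    gv_v50 = gv_curve$v50,
    gv_slope = gv_curve$s,
    threshold_class = classify_threshold(gv_curve$v50),
    inactivation_class = inact_class
  )
}

# First-appearance voltage: most hyperpolarized step whose steady current
# exceeds `rel` of the steady current at the most depolarized step.
.first_appearance <- function(recording, rel = 0.01) {
  protocol <- recording$protocol
  step <- .varying_epoch(protocol)
  t_on <- sum(protocol$epochs$duration[seq_len(step - 1)])
  t_off <- t_on + protocol$epochs$duration[[step]]
  idx <- which(recording$time >= t_on + 0.9 * (t_off - t_on) &
                 recording$time < t_off - 1e-9)
  v <- vapply(seq_len(protocol$n_sweeps),
              function(sw) epoch_voltages(protocol, sw)[[step]], numeric(1))
  steady <- vapply(seq_len(protocol$n_sweeps),
                   function(sw) abs(mean(recording$currents[sw, idx])), numeric(1))
  ref <- steady[[which.max(v)]]
  hit <- which(steady >= rel * ref)
  if (!length(hit)) return(NA_real_)
  min(v[hit])
}

# Tail-decay time constant at the fixed post-step tail of a family protocol.
.family_tail_tau <- function(recording, blank = 0.3) {
  protocol <- recording$protocol
  step <- .varying_epoch(protocol)
  t_repol <- sum(protocol$epochs$duration[seq_len(step)])
  sw <- protocol$n_sweeps  # most depolarized step: largest tail
  ta <- tail_amplitude(recording$time, recording$currents[sw, ], t_repol,
                       blank = blank)
  ta$tau
}

# Late-phase activation time constant at the most depolarized step.
.family_activation_tau <- function(recording) {
  protocol <- recording$protocol
  step <- .varying_epoch(protocol)
  t_on <- sum(protocol$epochs$duration[seq_len(step - 1)])
  t_off <- t_on + protocol$epochs$duration[[step]]
  sw <- protocol$n_sweeps
  res <- activation_delay_and_tau(recording$time, recording$currents[sw, ],
                                  t_on, t_off)
  res$tau_late
}

#' Compare heteromeric co-expression currents against the homomeric control
#'
#' Derives the qualitative phenotype flags of a regulatory-subunit
#' co-expression experiment:
#' \itemize{
#'   \item `inactivation` — from the pre-pulse difference trace
#'     ([prepulse_difference()]): `"none"` if no appreciable inactivating
#'     component, otherwise classified by the difference-trace decay time
#'     constant (`very_fast` < 15 ms, `fast` < 60 ms, `slow` otherwise).
#'   \item `threshold_shift` — hyperpolarizing shift of the first-appearance
#'     voltage (most hyperpolarized step with steady current above 1% of the
#'     top step): 10 mV `"small"`, 20 mV `"medium"`, >= 30 mV `"large"`.
#'   \item `activation_rate` / `deactivation_rate` — late-phase activation
#'     and tail-decay time-constant ratios mix/homomer (> 1.5 `"slow"`,
#'     < 0.67 `"fast"`).
#' }
#' Any property whose recordings are missing — or, for the activation rate,
#' whose measurement is obscured by fast heteromeric inactivation — is
#' reported `"undetermined"`.
#'
#' @param mix Named list of recordings for the co-expression: `family` (a
#'   `heteromer_family` recording) and/or `prepulse` (a two-sweep
#'   `heteromer_prepulse` recording).
#' @param homomer Named list with the homomeric control `family` recording
#'   (required when `mix$family` is given).
#' @param cutoffs Calibration constants: list with `tau_very_fast`,
#'   `tau_fast` (ms), `shift_small`, `shift_medium`, `shift_large` (mV),
#'   `ratio_slow`, `ratio_fast`, `min_inact_amplitude` (fraction of peak).
#' @return A one-row `heteromer_report` tibble: `inactivation`,
#'   `threshold_shift`, `activation_rate`, `deactivation_rate`, plus the
#'   measured `inact_tau`, `shift_mV`, `activation_ratio`,
#'   `deactivation_ratio`.
#' @export
compare_heteromer <- function(mix, homomer = NULL,
                              cutoffs = heteromer_cutoffs()) {
  inact <- "undetermined"; inact_tau <- NA_real_
  if (!is.null(mix$prepulse)) {
    dp <- prepulse_difference(mix$prepulse)
    peak_main <- max(abs(dp$i_hyper))
    # the inactivating component is the POSITIVE part of the difference
    # (the hyperpolarized pre-pulse leaves more channels available); the
    # early negative excursion is the activation-history mismatch of the
    # non-inactivating background and is not an inactivating component
    pk <- which.max(dp$difference)
    if (dp$difference[[pk]] < cutoffs$min_inact_amplitude * peak_main) {
      inact <- "none"
    } else {
      dfit <- fit_exponential(dp$time_ms[pk:nrow(dp)], dp$difference[pk:nrow(dp)])
      inact_tau <- dfit$tau
      inact <- if (inact_tau < cutoffs$tau_very_fast) "very_fast"
               else if (inact_tau < cutoffs$tau_fast) "fast"
               else "slow"
    }
  }

  shift <- "undetermined"; shift_mv <- NA_real_
  act <- "undetermined"; act_ratio <- NA_real_
  deact <- "undetermined"; deact_ratio <- NA_real_
  if (!is.null(mix$family)) {
    if (is.null(homomer$family)) abort("Missing homomeric control `family` recording.")
    v_mix <- .first_appearance(mix$family)
    v_hom <- .first_appearance(homomer$family)
    shift_mv <- v_hom - v_mix
    shift <- if (!is.finite(shift_mv) || shift_mv < cutoffs$shift_small) "none"
             else if (shift_mv < cutoffs$shift_medium) "small"
             else if (shift_mv < cutoffs$shift_large) "medium"
             else "large"

    deact_ratio <- .family_tail_tau(mix$family) / .family_tail_tau(homomer$family)
    deact <- if (deact_ratio > cutoffs$ratio_slow) "slow" else "none"

    fast_inact <- inact %in% c("fast", "very_fast")
    if (!fast_inact) {
      act_try <- tryCatch(
        .family_activation_tau(mix$family) / .family_activation_tau(homomer$family),
        error = function(e) NA_real_)
      if (is.finite(act_try)) {
        act_ratio <- act_try
        act <- if (act_ratio > cutoffs$ratio_slow) "slow"
               else if (act_ratio < cutoffs$ratio_fast) "fast"
               else "none"
      }
    }
  }

  structure(tibble::tibble(
    inactivation = inact, threshold_shift = shift,
    activation_rate = act, deactivation_rate = deact,
    inact_tau = inact_tau, shift_mV = shift_mv,
    activation_ratio = act_ratio, deactivation_ratio = deact_ratio
  ), class = c("heteromer_report", class(tibble::tibble())))
}

#' Calibration cutoffs for heteromer phenotype flags
#'
#' Stored as a configuration object rather than hard-coded: the published
#' separations are qualitative (complete inactivation within ~1 s vs within
#' 50 ms; threshold shifts on a 10-mV protocol grid).
#' @return A named list of cutoffs.
#' @export
heteromer_cutoffs <- function() {
  list(tau_very_fast = 15, tau_fast = 60,
       shift_small = 10, shift_medium = 20, shift_large = 30,
       ratio_slow = 1.5, ratio_fast = 0.67,
       min_inact_amplitude = 0.02)
}

#' Recover the summary table of all registered channels end-to-end
#'
#' For each acceptance-grade fixture, simulates the protocols used in
#' characterization (noiseless; isochronal-tail GV on the truncated
#' construct in symmetrical K+, steady-state inactivation with 5-s
#' pre-pulses, +60 mV inactivation decay in instantaneous-activation mode)
#' and runs the full fitting pipeline, reporting recovered next to
#' configured values with pass/fail at the stated tolerances.
#'
#' @param names Fixture names (default: the six acceptance-grade entries).
#' @param tol_v50,tol_slope,tol_tau_rel Recovery tolerances: mV, mV,
#'   relative.
#' @return A tibble with one row per recovered quantity: `channel`,
#'   `quantity`, `configured`, `recovered`, `tolerance`, `pass`.
#' @export
reproduce_table1 <- function(names = paste0("NvShak", 1:6),
                             tol_v50 = 0.5, tol_slope = 0.2,
                             tol_tau_rel = 0.02) {
  rows <- list()
  add <- function(channel, quantity, configured, recovered, tol) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      channel = channel, quantity = quantity, configured = configured,
      recovered = recovered, tolerance = tol,
      pass = is.finite(recovered) && abs(recovered - configured) <= tol)
  }
  for (nm in names) {
    fx <- kv_fixture(nm)
    res <- characterize_fixture(nm)
    add(nm, "gv_v50", fx$activation$v50, res$gv$v50, tol_v50)
    add(nm, "gv_slope", fx$activation$s, res$gv$s, tol_slope)
    comps <- fx$inactivation
    if (length(comps)) {
      add(nm, "ssi_v50", comps[[1]]$v50, res$ssi$v50, tol_v50)
      add(nm, "ssi_slope", comps[[1]]$s, res$ssi$s, tol_slope)
      taus <- sort(vapply(comps, `[[`, numeric(1), "tau_inact"))
      rec_taus <- sort(res$tau$tau)
      if (nm == "NvShak6") next  # partial inactivation: no published tau
      if (length(taus) == length(rec_taus)) {
        for (k in seq_along(taus)) {
          add(nm, paste0("tau_inact", if (length(taus) > 1) k else ""),
              taus[[k]], rec_taus[[k]], tol_tau_rel * taus[[k]])
        }
      } else {
        add(nm, "tau_inact", taus[[1]], NA_real_, tol_tau_rel * taus[[1]])
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate and analyze one fixture through the characterization pipeline
#'
#' The workhorse behind [reproduce_table1()]: noiseless simulations of the
#' GV (isochronal tails of the truncated construct in symmetrical K+), SSI
#' (5-s pre-pulses) and +60 mV inactivation-decay protocols, analyzed with
#' [build_gv_curve()], [build_ssi_curve()] and
#' [select_inactivation_model()].
#'
#' @param name Fixture name.
#' @param n_cells Number of (identical, noiseless) cells to simulate for the
#'   GV/SSI curves.
#' @param inact_step_ms Duration of the +60 mV inactivation step, ms.
#' @return A list: `gv` (gv_curve), `ssi` (ssi_curve or NULL), `tau`
#'   (tibble tau/fraction or NULL), `selection`, `summary` (the
#'   [summarize_channel()] row).
#' @export
characterize_fixture <- function(name, n_cells = 1L, inact_step_ms = 600) {
  fx <- kv_fixture(name)
  has_inact <- length(fx$inactivation) > 0
  has_ntype <- any(vapply(fx$inactivation, function(cp) cp$mechanism == "N_type",
                          logical(1)))

  # GV: truncated construct where truncation removes N-type inactivation
  gv_model <- kv_fixture(name, truncated = has_ntype)
  gv_cells <- lapply(seq_len(n_cells), function(ci) {
    simulate_sweeps(gv_model, build_protocol("gv_tail"),
                    solutions = symmetrical_k_solutions())
  })
  gv <- build_gv_curve(gv_cells)

  ssi <- NULL
  if (has_inact) {
    ssi_cells <- lapply(seq_len(n_cells), function(ci) {
      simulate_sweeps(fx, build_protocol("ssi"), solutions = standard_solutions())
    })
    ssi <- build_ssi_curve(ssi_cells)
  }

  tau_tbl <- NULL; sel <- NULL
  if (has_inact) {
    step_rec <- simulate_sweeps(
      fx, build_protocol("activation_family", step_start = 60, n_sweeps = 1,
                         step_duration = inact_step_ms),
      solutions = standard_solutions(), mode = "instantaneous_activation")
    dec <- .decay_trace(step_rec, 60)
    sel <- select_inactivation_model(dec$t, dec$i)
    tau_tbl <- if (sel$n_components == 2L) {
      tibble::tibble(tau = c(sel$double$tau1, sel$double$tau2),
                     fraction = c(sel$double$f1, sel$double$f2))
    } else {
      tibble::tibble(tau = sel$single$tau, fraction = 1)
    }
  }

  summary <- tibble::tibble(
    name = name,
    gv_v50 = gv$v50, gv_slope = gv$s,
    ssi_v50 = if (!is.null(ssi)) ssi$v50 else NA_real_,
    ssi_slope = if (!is.null(ssi)) ssi$s else NA_real_,
    threshold_class = classify_threshold(gv$v50)
  )
  list(gv = gv, ssi = ssi, tau = tau_tbl, selection = sel, summary = summary)
}
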