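# Identify the sweep-varying epoch of a protocol (the "step").
.varying_epoch <- function(protocol) {
  idx <- which(abs(protocol$epochs$v_inc) > 0)
  if (!length(idx)) abort("Protocol has no sweep-varying epoch.")
  idx[[1]]
}

#' Conductance-voltage (GV) curve from isochronal tail currents
#'
#' For each cell, tail-current amplitudes (back-extrapolated to the instant
#' of repolarization, [tail_amplitude()]) are converted to conductances by
#' dividing by the tail driving force, normalized to that cell's maximum,
#' and fitted with the normalized increasing Boltzmann
#' `G/Gmax = 1/(1 + exp(-(V - v50)/s))`. The reported `v50` and `s` are the
#' means of the per-cell fits; displayed points are mean +/- SEM across
#' cells.
#'
#' @param recordings A `sweep_recording` (one cell) or list of them (cells),
#'   recorded with the `gv_tail` protocol (hold, sweep-varying step, fixed
#'   tail); symmetrical high-K+ solutions are the usual condition.
#' @param blank Settling blank after repolarization, ms.
#' @return A `gv_curve`: list with `data` (tibble: voltage, mean, sem, n),
#'   `v50`, `s`, `fit` (a normalized `boltzmann_fit` at the mean
#'   parameters), `per_cell` (per-cell fits tibble).
#' @export
build_gv_curve <- function(recordings, blank = 0.3) {
  cells <- if (inherits(recordings, "sweep_recording")) list(recordings) else recordings
  stopifnot(length(cells) >= 1,
            all(vapply(cells, inherits, logical(1), "sweep_recording")))
  protocol <- cells[[1]]$protocol
  step <- .varying_epoch(protocol)
  tail_epoch <- step + 1L
  if (tail_epoch > nrow(protocol$epochs)) abort("gv_tail protocol needs a tail epoch after the step.")
  t_repol <- sum(protocol$epochs$duration[seq_len(step)])

  per_cell <- purrr::map_dfr(seq_along(cells), function(ci) {
    rec <- cells[[ci]]
    e_k <- nernst_potential(rec$solutions)
    v_tail <- rec$protocol$epochs$v_start[[tail_epoch]]
    drive <- v_tail - e_k
    if (abs(drive) < 1e-6) abort("Tail voltage equals the reversal potential; no driving force.")
    rows <- purrr::map_dfr(seq_len(rec$protocol$n_sweeps), function(sw) {
      v_step <- epoch_voltages(rec$protocol, sw)[[step]]
      ta <- tail_amplitude(rec$time, rec$currents[sw, ], t_repol, blank = blank)
      tibble::tibble(voltage = v_step, g = ta$amplitude / drive)
    })
    rows$g_norm <- rows$g / max(rows$g)
    fit <- fit_boltzmann(rows$voltage, rows$g_norm, normalized = TRUE,
                         direction = "increasing")
    tibble::tibble(cell = ci, voltage = rows$voltage, g_norm = rows$g_norm,
                   v50 = fit$v50, s = fit$s)
  })

  .finish_curve(per_cell, value_col = "g_norm", direction = "increasing",
                class = "gv_curve")
}

#' Steady-state inactivation (SSI) curve
#'
#' For each cell, the peak test-pulse current (maximum absolute current
#' after a short blanking window) following each conditioning pre-pulse is
#' normalized to that cell's maximum and fitted with the normalized
#' decreasing Boltzmann `ped + (1 - ped)/(1 + exp((V - v50)/s))` (free
#' pedestal for partially inactivating channels).
#'
#' @param recordings A `sweep_recording` or list of them, from the `ssi`
#'   protocol (hold, sweep-varying pre-pulse, fixed test pulse, tail).
#' @param blank Blanking window after the test-pulse step, ms.
#' @return An `ssi_curve` (same structure as [build_gv_curve()]).
#' @export
build_ssi_curve <- function(recordings, blank = 0.3) {
  cells <- if (inherits(recordings, "sweep_recording")) list(recordings) else recordings
  stopifnot(length(cells) >= 1,
            all(vapply(cells, inherits, logical(1), "sweep_recording")))
  protocol <- cells[[1]]$protocol
  pre <- .varying_epoch(protocol)
  if (pre >= nrow(protocol$epochs)) abort("ssi protocol needs a test epoch after the pre-pulse.")
  # test pulse = most depolarized fixed epoch after the pre-pulse (skips any
  # deactivating interpulse)
  after <- seq(pre + 1L, nrow(protocol$epochs))
  test <- after[[which.max(protocol$epochs$v_start[after])]]
  t_test <- sum(protocol$epochs$duration[seq_len(test - 1L)])
  t_test_end <- t_test + protocol$epochs$duration[[test]]

  per_cell <- purrr::map_dfr(seq_along(cells), function(ci) {
    rec <- cells[[ci]]
    win <- rec$time >= t_test + blank - 1e-9 & rec$time < t_test_end - 1e-9
    rows <- purrr::map_dfr(seq_len(rec$protocol$n_sweeps), function(sw) {
      v_pre <- epoch_voltages(rec$protocol, sw)[[pre]]
      tibble::tibble(voltage = v_pre, peak = max(abs(rec$currents[sw, win])))
    })
    rows$avail <- rows$peak / max(rows$peak)
    fit <- fit_boltzmann(rows$voltage, rows$avail, normalized = TRUE,
                         direction = "decreasing")
    tibble::tibble(cell = ci, voltage = rows$voltage, avail = rows$avail,
                   v50 = fit$v50, s = fit$s, pedestal = fit$a2)
  })

  .finish_curve(per_cell, value_col = "avail", direction = "decreasing",
                class = "ssi_curve")
}

# Shared aggregation for GV/SSI curves.
.finish_curve <- function(per_cell, value_col, direction, class) {
  n_cells <- dplyr::n_distinct(per_cell$cell)
  data <- per_cell |>
    dplyr::group_by(.data$voltage) |>
    dplyr::summarise(
      mean = mean(.data[[value_col]]),
      sem = if (n_cells > 1) sd(.data[[value_col]]) / sqrt(n_cells) else NA_real_,
      n = n_cells, .groups = "drop") |>
    dplyr::arrange(.data$voltage)
  fits <- dplyr::distinct(per_cell, .data$cell, .keep_all = TRUE)
  v50 <- mean(fits$v50)
  s <- mean(fits$s)
  summary_fit <- structure(
    list(a1 = if (direction == "increasing") 0 else 1,
         a2 = if (direction == "increasing") 1 else mean(fits$pedestal %||% 0),
         v50 = v50, s = s, rss = NA_real_, converged = TRUE,
         low_confidence = FALSE, normalized = TRUE, direction = direction,
         diagnostics = NULL,
         data = data.frame(v = data$voltage, g = data$mean)),
    class = "boltzmann_fit")
  structure(list(data = data, v50 = v50, s = s, fit = summary_fit,
                 per_cell = per_cell, n_cells = n_cells),
            class = c(class, "vclamp_curve"))
}

#' @export
print.vclamp_curve <- function(x, ...) {
  kind <- if (inherits(x, "gv_curve")) "GV" else "SSI"
  cat(sprintf("<%s curve> V50 = %.2f mV, s = %.2f mV (n = %d cell%s)\n",
              kind, x$v50, x$s, x$n_cells, if (x$n_cells == 1) "" else "s"))
  print(x$data, n = 5)
  invisible(x)
}

#' Isolate the inactivating (heteromeric) current component
#'
#' Subtracts the current following a depolarized conditioning pre-pulse
#' (which removes inactivating heteromeric channels, leaving the
#' non-inactivating homomeric component) from the current following a
#' hyperpolarized pre-pulse, sample-wise, after aligning both traces on
#' their pre-pulse-end baselines. When the homomer does not inactivate and
#' the heteromer inactivates fully, the difference equals the pure
#' heteromeric current.
#'
#' @param i_hyper,i_depol Current traces (nA) from identical test-pulse
#'   epochs after hyperpolarized / depolarized pre-pulses.
#' @param baseline Optional integer indices of pre-test baseline samples
#'   used for alignment; `NULL` skips alignment (already-aligned traces).
#' @return The difference trace (nA), same length as the inputs.
#' @export
isolate_inactivating_component <- function(i_hyper, i_depol, baseline = NULL) {
  if (length(i_hyper) != length(i_depol)) {
    abort("Trace length mismatch between hyperpolarized and depolarized sweeps.")
  }
  if (!is.null(baseline) && length(baseline)) {
    i_hyper <- i_hyper - mean(i_hyper[baseline])
    i_depol <- i_depol - mean(i_depol[baseline])
  }
  i_hyper - i_depol
}

#' Pre-pulse subtraction on a two-sweep recording
#'
#' Convenience wrapper around [isolate_inactivating_component()] for a
#' `heteromer_prepulse` recording (sweep 1 hyperpolarized, sweep 2
#' depolarized pre-pulse). The hyperpolarized sweep is zeroed on its
#' pre-pulse-end baseline (channels closed at the hyperpolarized pre-pulse,
#' so that level is true zero); the depolarized sweep — whose pre-pulse-end
#' level contains steady open-channel current — is aligned so its
#' late-test-pulse steady level matches the hyperpolarized sweep's, the
#' level at which the two traces superimpose once the inactivating
#' component has decayed. The returned difference therefore decays to zero
#' and vanishes identically when no heteromeric channels are present.
#'
#' @param recording A two-sweep `sweep_recording` from the
#'   `heteromer_prepulse` protocol.
#' @return A tibble: `time_ms` (re-referenced to test-pulse start),
#'   `i_hyper`, `i_depol`, `difference` (nA).
#' @export
prepulse_difference <- function(recording) {
  stopifnot(inherits(recording, "sweep_recording"))
  if (nrow(recording$currents) < 2) abort("Pre-pulse subtraction needs both sweeps.")
  protocol <- recording$protocol
  pre <- .varying_epoch(protocol)
  t_test <- sum(protocol$epochs$duration[seq_len(pre)])
  t_test_end <- t_test + protocol$epochs$duration[[pre + 1L]]
  base_idx <- which(recording$time >= t_test - 1 & recording$time < t_test - 1e-9)
  test_idx <- which(recording$time >= t_test - 1e-9 & recording$time < t_test_end - 1e-9)
  late_idx <- tail(test_idx, max(3L, length(test_idx) %/% 10))
  hyper <- recording$currents[1, ] - mean(recording$currents[1, base_idx])
  depol <- recording$currents[2, ]
  depol <- depol - (mean(depol[late_idx]) - mean(hyper[late_idx]))
  tibble::tibble(
    time_ms = recording$time[test_idx] - t_test,
    i_hyper = hyper[test_idx],
    i_depol = depol[test_idx],
    difference = isolate_inactivating_component(hyper, depol)[test_idx]
  )
}
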