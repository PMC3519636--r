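#' Epoch-structured voltage protocol
#'
#' A protocol is an ordered list of constant-voltage epochs; an epoch's
#' voltage may vary across sweeps on an arithmetic grid (`v_start` plus
#' `(sweep - 1) * v_inc`). All sweeps share the same time base with sampling
#' interval `dt`.
#'
#' @param name Protocol label.
#' @param dt Sampling interval, ms.
#' @param epochs A data frame (or tibble) with columns `duration` (ms),
#'   `v_start` (mV) and `v_inc` (mV per sweep; 0 for a fixed epoch).
#' @param n_sweeps Number of sweeps.
#' @param holding Holding potential before the first epoch, mV.
#' @return A `voltage_protocol` object.
#' @export
voltage_protocol <- function(name, dt, epochs, n_sweeps, holding = -100) {
  epochs <- tibble::as_tibble(epochs)
  stopifnot(all(c("duration", "v_start", "v_inc") %in% names(epochs)))
  if (any(epochs$duration <= 0)) abort("Epoch durations must be > 0 ms.")
  if (dt <= 0) abort("`dt` must be > 0 ms.")
  if (n_sweeps < 1) abort("`n_sweeps` must be >= 1.")
  structure(
    list(name = name, dt = dt, epochs = epochs,
         n_sweeps = as.integer(n_sweeps), holding = holding),
    class = "voltage_protocol"
  )
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s: %d sweeps, dt %g ms, hold %g mV, %d epochs (%g ms total)\n",
              x$name, x$n_sweeps, x$dt, x$holding, nrow(x$epochs), sum(x$epochs$duration)))
  invisible(x)
}

#' Epoch voltages resolved for one sweep
#'
#' @param protocol A [voltage_protocol()].
#' @param sweep Sweep index (1-based).
#' @return Numeric vector of epoch voltages, mV.
#' @export
epoch_voltages <- function(protocol, sweep) {
  stopifnot(inherits(protocol, "voltage_protocol"),
            sweep >= 1, sweep <= protocol$n_sweeps)
  protocol$epochs$v_start + (sweep - 1) * protocol$epochs$v_inc
}

#' Sample times of a protocol
#' @param protocol A [voltage_protocol()].
#' @return Time vector in ms starting at 0 (sweep start), step `dt`.
#' @export
protocol_times <- function(protocol) {
  total <- sum(protocol$epochs$duration)
  n <- floor(total / protocol$dt + 1e-9)
  (seq_len(n) - 1) * protocol$dt
}

#' Command-voltage trace of one sweep
#'
#' @inheritParams epoch_voltages
#' @return Voltage at every sample time, mV.
#' @export
voltage_trace <- function(protocol, sweep) {
  v_epochs <- epoch_voltages(protocol, sweep)
  time <- protocol_times(protocol)
  bounds <- cumsum(protocol$epochs$duration)
  idx <- findInterval(time, c(0, head(bounds, -1)), left.open = FALSE)
  v_epochs[pmin(idx, length(v_epochs))]
}

#' Build one of the standard voltage protocols
#'
#' Presets for the protocol families used in functional characterization of
#' Shaker-type channels:
#' \describe{
#'   \item{activation_family}{13 sweeps of 100-ms steps from -60 to +60 mV
#'     in 10-mV increments from a -100 mV hold, with a post-step tail at the
#'     holding potential.}
#'   \item{gv_tail}{Same step family as `activation_family`; the tail epoch
#'     at -100 mV is the measured isochronal tail for conductance-voltage
#'     analysis.}
#'   \item{ssi}{5-s conditioning pre-pulses over a -120..0 mV grid followed
#'     by a +60 mV test pulse (steady-state inactivation). A brief
#'     deactivating interpulse at -120 mV separates pre-pulse and test
#'     pulse so channels opened by depolarized pre-pulses close before the
#'     test; availability recovered during it is affine in the conditioned
#'     availability and is absorbed by the free pedestal of the SSI fit
#'     (set `gap_duration = 0` to omit it).}
#'   \item{deactivation_tails}{A +50 mV activating pulse followed by tail
#'     epochs at -160, -140, -120, -100 and -80 mV.}
#'   \item{heteromer_family}{400-ms steps from -20 to +20 mV in 10-mV
#'     increments with a -40 mV tail (whole-cell co-expression assay).}
#'   \item{heteromer_prepulse}{Two sweeps with 5-s pre-pulses at -100 mV
#'     (hyperpolarized) and +20 mV (depolarized) followed by a long +60 mV
#'     test pulse, for pre-pulse subtraction of heteromeric current.}
#' }
#'
#' @param kind One of the preset names above.
#' @param holding Holding potential, mV.
#' @param dt Sampling interval, ms (preset-specific default).
#' @param n_sweeps,step_start,step_increment,step_duration Overrides for the
#'   varying step epoch.
#' @param hold_duration Duration of the initial epoch at holding, ms.
#' @param tail_voltage,tail_duration Overrides for the tail epoch.
#' @param prepulse_duration,test_voltage,test_duration Overrides for the
#'   ssi/heteromer_prepulse presets.
#' @param gap_duration,gap_voltage Deactivating interpulse between pre-pulse
#'   and test pulse of the ssi preset, ms / mV (0 ms omits it).
#' @return A [voltage_protocol()].
#' @examples
#' build_protocol("activation_family")
#' build_protocol("ssi")$epochs
#' @export
build_protocol <- function(kind = c("activation_family", "ssi", "gv_tail",
                                    "deactivation_tails", "heteromer_family",
                                    "heteromer_prepulse"),
                           holding = -100, dt = NULL, n_sweeps = NULL,
                           step_start = NULL, step_increment = NULL,
                           step_duration = NULL, hold_duration = 5,
                           tail_voltage = NULL, tail_duration = NULL,
                           prepulse_duration = 5000,
                           test_voltage = 60, test_duration = NULL,
                           gap_duration = 50, gap_voltage = -120) {
  kind <- match.arg(kind)
  ep <- function(duration, v_start, v_inc = 0) {
    tibble::tibble(duration = duration, v_start = v_start, v_inc = v_inc)
  }
  switch(kind,
    activation_family = ,
    gv_tail = {
      dt <- dt %||% 0.05
      n_sweeps <- n_sweeps %||% 13L
      epochs <- dplyr::bind_rows(
        ep(hold_duration, holding),
        ep(step_duration %||% 100, step_start %||% -60, step_increment %||% 10),
        ep(tail_duration %||% 50, tail_voltage %||% holding)
      )
      voltage_protocol(kind, dt, epochs, n_sweeps, holding)
    },
    ssi = {
      dt <- dt %||% 0.1
      n_sweeps <- n_sweeps %||% 13L
      epochs <- dplyr::bind_rows(
        ep(hold_duration, holding),
        ep(prepulse_duration, step_start %||% -120, step_increment %||% 10),
        if (gap_duration > 0) ep(gap_duration, gap_voltage),
        ep(test_duration %||% 100, test_voltage),
        ep(tail_duration %||% 20, tail_voltage %||% holding)
      )
      voltage_protocol(kind, dt, epochs, n_sweeps, holding)
    },
    deactivation_tails = {
      dt <- dt %||% 0.05
      n_sweeps <- n_sweeps %||% 5L
      epochs <- dplyr::bind_rows(
        ep(hold_duration, holding),
        ep(step_duration %||% 20, 50),
        ep(tail_duration %||% 100, tail_voltage %||% -160, step_increment %||% 20)
      )
      voltage_protocol(kind, dt, epochs, n_sweeps, holding)
    },
    heteromer_family = {
      dt <- dt %||% 0.1
      n_sweeps <- n_sweeps %||% 5L
      epochs <- dplyr::bind_rows(
        ep(hold_duration, holding),
        ep(step_duration %||% 400, step_start %||% -20, step_increment %||% 10),
        ep(tail_duration %||% 100, tail_voltage %||% -40)
      )
      voltage_protocol(kind, dt, epochs, n_sweeps, holding)
    },
    heteromer_prepulse = {
      dt <- dt %||% 0.1
      epochs <- dplyr::bind_rows(
        ep(hold_duration, holding),
        ep(prepulse_duration, step_start %||% -100, step_increment %||% 120),
        ep(test_duration %||% 1000, test_voltage),
        ep(tail_duration %||% 20, tail_voltage %||% holding)
      )
      voltage_protocol(kind, dt, epochs, n_sweeps %||% 2L, holding)
    }
  )
}

#' Read or write a protocol as JSON
#'
#' @param protocol A [voltage_protocol()].
#' @param path File path.
#' @return `read_protocol()` returns a [voltage_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  obj <- list(name = protocol$name, dt = protocol$dt,
              n_sweeps = protocol$n_sweeps, holding = protocol$holding,
              epochs = as.data.frame(protocol$epochs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "dt", "n_sweeps", "holding", "epochs")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    abort(sprintf("Protocol file %s is missing field(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  voltage_protocol(obj$name, obj$dt, obj$epochs, obj$n_sweeps, obj$holding)
}
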