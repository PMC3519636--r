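#' Write a recording in the episodic-sweep text format
#'
#' Tab-delimited text: `#key<TAB>value` metadata lines (protocol, sampling
#' interval, solutions, units, provenance), then a header row `time_ms`
#' followed by one `sweep_<k>_nA` column per sweep. Numeric values are
#' printed at 9 significant digits with ASCII minus signs, so
#' write-read-write round-trips are bit-identical.
#'
#' @param recording A `sweep_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(recording, path) {
  stopifnot(inherits(recording, "sweep_recording"))
  p <- recording$protocol
  fmt <- function(x) sprintf("%.9g", x)
  header <- c(
    "#format\tkvclamp-episodic-sweeps-v1",
    paste0("#protocol\t", p$name),
    paste0("#dt\t", fmt(p$dt)),
    paste0("#n_sweeps\t", p$n_sweeps),
    paste0("#holding\t", fmt(p$holding)),
    paste0("#epochs\t", jsonlite::toJSON(as.data.frame(p$epochs), digits = NA)),
    paste0("#k_in\t", fmt(recording$solutions$k_in)),
    paste0("#k_out\t", fmt(recording$solutions$k_out)),
    paste0("#temperature\t", fmt(recording$solutions$temperature)),
    "#units\ttime=ms current=nA voltage=mV",
    paste0("#model\t", recording$provenance$model_name %||% "unknown"),
    paste0("#mode\t", recording$provenance$mode %||% "unknown"),
    paste0("#seed\t", recording$provenance$seed %||% 0L)
  )
  n_sw <- nrow(recording$currents)
  col_head <- paste(c("time_ms", sprintf("sweep_%d_nA", seq_len(n_sw))),
                    collapse = "\t")
  body <- vapply(seq_along(recording$time), function(k) {
    paste(c(fmt(recording$time[[k]]), fmt(recording$currents[, k])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, col_head, body), path)
  invisible(path)
}

#' Read a recording from the episodic-sweep text format
#'
#' @param path Input file path (written by [write_sweeps()] or conforming
#'   to the same dialect).
#' @return A `sweep_recording`.
#' @export
read_sweeps <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  kv <- strsplit(sub("^#", "", meta_lines), "\t", fixed = TRUE)
  bad <- which(lengths(kv) < 2)
  if (length(bad)) {
    abort(sprintf("Malformed metadata at line %d of %s: expected '#key<TAB>value'.",
                  which(is_meta)[bad[[1]]], path))
  }
  meta <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "\t"), character(1)),
                   vapply(kv, `[[`, character(1), 1))
  for (key in c("dt", "n_sweeps", "holding", "epochs", "k_in", "k_out", "temperature")) {
    if (!key %in% names(meta)) {
      abort(sprintf("Missing required metadata key '#%s' in %s.", key, path))
    }
  }
  epochs <- jsonlite::fromJSON(meta[["epochs"]])
  protocol <- voltage_protocol(meta[["protocol"]] %||% "imported",
                               as.numeric(meta[["dt"]]), epochs,
                               as.integer(meta[["n_sweeps"]]),
                               as.numeric(meta[["holding"]]))
  solutions <- solution_pair(as.numeric(meta[["k_in"]]), as.numeric(meta[["k_out"]]),
                             as.numeric(meta[["temperature"]]))

  data_lines <- lines[!is_meta]
  if (length(data_lines) < 2) abort(sprintf("No sweep data found in %s.", path))
  cols <- strsplit(data_lines[[1]], "\t", fixed = TRUE)[[1]]
  n_sw <- as.integer(meta[["n_sweeps"]])
  if (length(cols) != n_sw + 1L) {
    abort(sprintf("Column count mismatch in %s: header declares %d sweeps but found %d data columns.",
                  path, n_sw, length(cols) - 1L))
  }
  first_data_line <- which(!is_meta)[2]
  rows <- strsplit(data_lines[-1], "\t", fixed = TRUE)
  nbad <- which(lengths(rows) != n_sw + 1L)
  if (length(nbad)) {
    abort(sprintf("Column count mismatch at line %d of %s.",
                  first_data_line + nbad[[1]] - 1L, path))
  }
  mat <- matrix(as.numeric(unlist(rows)), nrow = n_sw + 1L)
  if (anyNA(mat)) abort(sprintf("Non-numeric sweep data in %s.", path))
  structure(
    list(time = mat[1, ], currents = mat[-1, , drop = FALSE],
         protocol = protocol, solutions = solutions,
         provenance = list(model = NULL,
                           model_name = meta[["model"]] %||% "imported",
                           mode = meta[["mode"]] %||% "unknown",
                           artifacts = NULL,
                           seed = as.integer(meta[["seed"]] %||% 0L),
                           leak_subtracted = FALSE,
                           source_file = path)),
    class = "sweep_recording"
  )
}

#' Write or read gating parameter sets as a key/value config
#'
#' One channel per block: a `[name]` header line followed by `key = value`
#' lines; inactivation components are indexed (`inact1_mechanism`, ...).
#'
#' @param models A [gating_params()] or list of them.
#' @param path File path.
#' @return `write_gating_config()` returns `path` invisibly;
#'   `read_gating_config()` returns a named list of [gating_params()].
#' @export
write_gating_config <- function(models, path) {
  if (inherits(models, "gating_params")) models <- list(models)
  fmt <- function(x) sprintf("%.9g", x)
  out <- character(0)
  for (m in models) {
    stopifnot(inherits(m, "gating_params"))
    a <- m$activation; d <- m$deactivation
    block <- c(
      sprintf("[%s]", m$name),
      paste0("g_max = ", fmt(m$g_max)),
      paste0("truncated = ", tolower(m$truncated)),
      paste0("v50_a = ", fmt(a$v50)), paste0("s_a = ", fmt(a$s)),
      paste0("n_gates = ", a$n_gates),
      paste0("tau_act_ref = ", fmt(a$tau_act_ref)),
      paste0("tau_act_vslope = ", fmt(a$tau_act_vslope)),
      paste0("tau_deact_ref = ", fmt(d$tau_deact_ref)),
      paste0("tau_deact_vslope = ", fmt(d$tau_deact_vslope))
    )
    for (j in seq_along(m$inactivation)) {
      cp <- m$inactivation[[j]]
      pre <- sprintf("inact%d_", j)
      block <- c(block,
        paste0(pre, "mechanism = ", cp$mechanism),
        paste0(pre, "tau_inact = ", fmt(cp$tau_inact)),
        paste0(pre, "fraction = ", fmt(cp$fraction)),
        paste0(pre, "v50 = ", fmt(cp$v50)),
        paste0(pre, "s = ", fmt(cp$s)),
        paste0(pre, "tau_recovery = ", fmt(cp$tau_recovery)),
        paste0(pre, "k_half_external = ", fmt(cp$k_half_external)))
    }
    out <- c(out, block, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_gating_config
#' @export
read_gating_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^\\[.+\\]$", lines)
  if (!length(starts)) abort(sprintf("No channel blocks found in %s.", path))
  ends <- c(starts[-1] - 1L, length(lines))
  models <- list()
  for (b in seq_along(starts)) {
    nm <- sub("^\\[(.+)\\]$", "\\1", lines[[starts[[b]]]])
    body <- lines[seq(starts[[b]] + 1L, ends[[b]])]
    kvs <- strsplit(body, "\\s*=\\s*")
    vals <- setNames(vapply(kvs, `[[`, character(1), 2),
                     vapply(kvs, `[[`, character(1), 1))
    num <- function(k, default = NULL) {
      if (k %in% names(vals)) as.numeric(vals[[k]]) else default
    }
    comps <- list()
    j <- 1L
    while (sprintf("inact%d_mechanism", j) %in% names(vals)) {
      pre <- sprintf("inact%d_", j)
      comps[[j]] <- inact_component(
        mechanism = vals[[paste0(pre, "mechanism")]],
        tau_inact = num(paste0(pre, "tau_inact")),
        fraction = num(paste0(pre, "fraction"), 1),
        v50 = num(paste0(pre, "v50")),
        s = num(paste0(pre, "s")),
        tau_recovery = num(paste0(pre, "tau_recovery"), 100),
        k_half_external = num(paste0(pre, "k_half_external"), 5))
      j <- j + 1L
    }
    models[[nm]] <- gating_params(
      nm, g_max = num("g_max", 1),
      activation = activation_params(
        v50 = num("v50_a"), s = num("s_a"),
        n_gates = as.integer(num("n_gates", 4)),
        tau_act_ref = num("tau_act_ref", 1),
        tau_act_vslope = num("tau_act_vslope", 80)),
      deactivation = deactivation_params(
        tau_deact_ref = num("tau_deact_ref", 5),
        tau_deact_vslope = num("tau_deact_vslope", 40)),
      inactivation = comps,
      truncated = identical(vals[["truncated"]], "true"))
  }
  models
}
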