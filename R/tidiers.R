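#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy summaries of fitted objects
#'
#' `tidy()` returns one row per fitted parameter; `glance()` returns a
#' one-row model summary with the residual sum of squares and convergence
#' status.
#'
#' @param x A `boltzmann_fit`, `exp_fit`, `double_exp_fit` or
#'   `inact_model_selection`.
#' @param ... Unused.
#' @return A tibble.
#' @name kvclamp-tidiers
NULL

#' @rdname kvclamp-tidiers
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a1", "a2", "v50", "s"),
    estimate = c(x$a1, x$a2, x$v50, x$s),
    unit = c("", "", "mV", "mV")
  )
}

#' @rdname kvclamp-tidiers
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged,
                 low_confidence = x$low_confidence,
                 normalized = x$normalized, direction = x$direction,
                 n = nrow(x$data))
}

#' @rdname kvclamp-tidiers
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("i_i", "a", "tau"),
    estimate = c(x$i_i, x$a, x$tau),
    unit = c("nA", "nA", "ms")
  )
}

#' @rdname kvclamp-tidiers
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, n = nrow(x$data))
}

#' @rdname kvclamp-tidiers
#' @export
tidy.double_exp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("i_i", "a1", "tau1", "f1", "a2", "tau2", "f2"),
    estimate = c(x$i_i, x$a1, x$tau1, x$f1, x$a2, x$tau2, x$f2),
    unit = c("nA", "nA", "ms", "", "nA", "ms", "")
  )
}

#' @rdname kvclamp-tidiers
#' @export
glance.double_exp_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, n = nrow(x$data))
}

#' @rdname kvclamp-tidiers
#' @export
tidy.inact_model_selection <- function(x, ...) {
  if (x$n_components == 2L) tidy(x$double) else tidy(x$single)
}

#' @rdname kvclamp-tidiers
#' @export
glance.inact_model_selection <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, f_stat = x$f_stat,
                 p_value = x$p_value)
}
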