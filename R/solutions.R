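#' Recording-solution ion concentrations
#'
#' Describes the potassium concentrations on either side of the membrane and
#' the recording temperature. These set the K+ reversal potential via
#' [nernst_potential()] and the external-K+ sensitivity of C-type
#' inactivation.
#'
#' @param k_in Internal (bath, cytoplasmic-face) K+ concentration, mM.
#' @param k_out External (pipette) K+ concentration, mM.
#' @param temperature Temperature, kelvin.
#'
#' @return An object of class `solution_pair`.
#' @examples
#' solution_pair(k_in = 140, k_out = 2)          # standard excised-patch bath/pipette
#' solution_pair(k_in = 140, k_out = 140)        # symmetrical K+, E_K = 0
#' @export
solution_pair <- function(k_in = 140, k_out = 2, temperature = 295) {
  if (!is.numeric(k_in) || k_in <= 0) abort("`k_in` must be a positive concentration (mM).")
  if (!is.numeric(k_out) || k_out <= 0) abort("`k_out` must be a positive concentration (mM).")
  if (!is.numeric(temperature) || temperature <= 0) abort("`temperature` must be positive kelvin.")
  structure(
    list(k_in = as.numeric(k_in), k_out = as.numeric(k_out),
         temperature = as.numeric(temperature)),
    class = "solution_pair"
  )
}

#' @export
print.solution_pair <- function(x, ...) {
  cat(sprintf("<solution_pair> K+ in %g mM / out %g mM, %g K (E_K = %.1f mV)\n",
              x$k_in, x$k_out, x$temperature, nernst_potential(x)))
  invisible(x)
}

#' Potassium reversal (Nernst) potential
#'
#' @param solutions A [solution_pair()].
#' @return Reversal potential in mV: `(RT/F) * log(k_out / k_in)`.
#' @examples
#' nernst_potential(solution_pair(140, 140))   # 0 mV in symmetrical K+
#' nernst_potential(solution_pair(140, 2))     # about -108 mV
#' @export
nernst_potential <- function(solutions) {
  stopifnot(inherits(solutions, "solution_pair"))
  .rt_over_f_mV(solutions$temperature) * log(solutions$k_out / solutions$k_in)
}

# Preset solutions used throughout: standard excised-patch (2 mM external K+)
# and symmetrical 140 mM K+ for tail-current work.
#' Common recording solutions
#'
#' `standard_solutions()` is the default excised-patch condition (140 mM
#' internal / 2 mM external K+); `symmetrical_k_solutions()` replaces external
#' Na+ with K+ (140/140) so tail currents are maximally inward and C-type
#' inactivation is suppressed.
#' @param temperature Temperature, kelvin.
#' @return A [solution_pair()].
#' @export
standard_solutions <- function(temperature = 295) solution_pair(140, 2, temperature)

#' @rdname standard_solutions
#' @export
symmetrical_k_solutions <- function(temperature = 295) solution_pair(140, 140, temperature)
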