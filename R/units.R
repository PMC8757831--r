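# Unit conventions
#
# All clinical quantities cross module boundaries in clinical units
# (cmH2O gauge, ml, l/min or l/s, bpm, % oxygen); the engine computes in
# absolute pascal, litres and seconds. Valve flow coefficients Kv are always
# quoted in m3/h/bar^0.5 (the water rating printed on specification sheets).
# Calibrated pneumatic pathways follow q [l/min] = a * (dp [mbar])^n with
# a = 13.1 * Kv; see `a_from_kv()`.

P_ATM_PA <- 101325
CMH2O_PA <- 98.0665
MBAR_PA <- 100
BAR_PA <- 1e5

#' Convert between clinical pressure units and pascal
#'
#' Helpers used throughout the package: lung mechanics are expressed in
#' cmH2O gauge (1 cmH2O = 98.0665 Pa), pneumatics in bar or mbar, and the
#' engine computes in absolute pascal (atmosphere = 101325 Pa).
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' cmh2o_to_pa(10.2)
#' pa_to_cmh2o(1000)
#' @export
cmh2o_to_pa <- function(x) x * CMH2O_PA

#' @rdname cmh2o_to_pa
#' @export
pa_to_cmh2o <- function(x) x / CMH2O_PA

#' @rdname cmh2o_to_pa
#' @export
bar_to_pa <- function(x) x * BAR_PA

#' @rdname cmh2o_to_pa
#' @export
pa_to_bar <- function(x) x / BAR_PA

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stopf("`%s` = %g must be in [%g, %g]", name, x, lower, upper)
  }
  invisible(as.numeric(x))
}
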