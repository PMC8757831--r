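# Test-lung mechanics: single-compartment R-C lungs with orifice-plate
# (parabolic) or linear resistance and volume-limited compliance, plus
# two-compartment parallel assemblies sharing the patient connector.

#' Test-lung compartment
#'
#' A single resistance-compliance compartment. Commercial test lungs use an
#' orifice-plate resistor, so the pressure drop is parabolic in flow,
#' `dp = k q^2`, with the rated resistance quoted at a reference flow
#' (60 l/min by default): `k = r_rated / q_ref`. A purely linear model
#' (`dp = r q`) is available via `resistance_model = "linear"`. The
#' compliance is volume-limited: below the usable bag volume `v0` the
#' leaf-spring casing sets `p = V / C`; beyond it, further expansion deforms
#' the much stiffer silicone bag and the incremental stiffness is multiplied
#' by `stiffening_factor`.
#'
#' @param r_rated rated resistance in cmH2O/(l/s) (>= 0).
#' @param c_lung compliance in ml/cmH2O (> 0).
#' @param v0_ml usable bag volume in ml (> 0), default 1000.
#' @param resistance_model `"parabolic"` (orifice plate, default) or
#'   `"linear"`.
#' @param rating_flow_lmin flow at which `r_rated` is quoted, default 60.
#' @param stiffening_factor incremental stiffness multiplier beyond `v0`
#'   (>= 1), default 50.
#' @param volume_ml initial volume above the relaxed state (>= 0).
#' @param label text label (e.g. `"R20/C20"`).
#' @return an object of class `vent_lung`.
#' @examples
#' lung_compartment(20, 20)
#' parse_lung("R20/C20")
#' @export
lung_compartment <- function(r_rated, c_lung, v0_ml = 1000,
                             resistance_model = c("parabolic", "linear"),
                             rating_flow_lmin = 60,
                             stiffening_factor = 50,
                             volume_ml = 0, label = NULL) {
  check_number(r_rated, "r_rated", lower = 0)
  check_number(c_lung, "c_lung", lower = 1e-6)
  check_number(v0_ml, "v0_ml", lower = 1)
  check_number(stiffening_factor, "stiffening_factor", lower = 1)
  check_number(volume_ml, "volume_ml", lower = 0)
  check_number(rating_flow_lmin, "rating_flow_lmin", lower = 1e-6)
  resistance_model <- match.arg(resistance_model)
  q_ref <- rating_flow_lmin / 60 # l/s
  if (resistance_model == "parabolic") {
    r_linear <- 0
    k_parabolic <- r_rated / q_ref
  } else {
    r_linear <- r_rated
    k_parabolic <- 0
  }
  if (r_linear <= 0 && k_parabolic <= 0) {
    stopf("compartment must have a non-zero resistance")
  }
  structure(
    list(
      r_rated = r_rated,
      r_linear = r_linear,
      k_parabolic = k_parabolic,
      c_lung = c_lung,
      v0_ml = v0_ml,
      stiffening_factor = stiffening_factor,
      volume_ml = volume_ml,
      resistance_model = resistance_model,
      label = label %||% sprintf("R%g/C%g", r_rated, c_lung)
    ),
    class = "vent_lung"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vent_lung <- function(x, ...) {
  cat(sprintf("<test lung %s: %s resistance, C %g ml/cmH2O, V0 %g ml>\n",
              x$label, x$resistance_model, x$c_lung, x$v0_ml))
  invisible(x)
}

#' Parse RX/CY test-lung shorthand
#'
#' `"R20/C20"` denotes a test lung with rated resistance 20 cmH2O/(l/s) and
#' compliance 20 ml/cmH2O.
#'
#' @param label shorthand string.
#' @param ... passed to [lung_compartment()].
#' @return a `vent_lung`.
#' @export
parse_lung <- function(label, ...) {
  m <- regmatches(label, regexec("^R([0-9.]+)/C([0-9.]+)$", label))[[1]]
  if (length(m) != 3L) stopf("cannot parse lung label '%s' (want 'R20/C20')",
                             label)
  lung_compartment(as.numeric(m[2]), as.numeric(m[3]), label = label, ...)
}

#' Two-compartment parallel assembly
#'
#' Two test lungs teed into the same patient connector. The shared connector
#' pressure drives both compartments through their own resistances, so the
#' compliances are not directly additive.
#'
#' @param ... one or two `vent_lung` compartments.
#' @param label optional label.
#' @return an object of class `vent_lung_assembly`.
#' @examples
#' lung_assembly(parse_lung("R20/C25"), parse_lung("R5/C30"))
#' @export
lung_assembly <- function(..., label = NULL) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1]]) &&
      !inherits(comps[[1]], "vent_lung")) {
    comps <- comps[[1]]
  }
  if (!length(comps) %in% 1:2 ||
      !all(vapply(comps, inherits, logical(1), "vent_lung"))) {
    stopf("`lung_assembly()` takes one or two `vent_lung` compartments")
  }
  structure(
    list(
      compartments = comps,
      label = label %||% paste(vapply(comps, `[[`, character(1), "label"),
                               collapse = " + ")
    ),
    class = "vent_lung_assembly"
  )
}

as_lung_assembly <- function(lung) {
  if (inherits(lung, "vent_lung_assembly")) return(lung)
  if (inherits(lung, "vent_lung")) return(lung_assembly(lung))
  if (is.character(lung) && length(lung) == 1L) {
    return(lung_assembly(parse_lung(lung)))
  }
  stopf("`lung` must be a vent_lung, a vent_lung_assembly or an 'R20/C20' string")
}

#' @export
print.vent_lung_assembly <- function(x, ...) {
  cat(sprintf("<lung assembly: %s>\n", x$label))
  invisible(x)
}

#' Lung recoil pressure
#'
#' Piecewise volume-limited elastance: `p = V / C` up to the usable bag
#' volume `v0`, then `p = v0/C + (V - v0) * stiffening_factor / C`;
#' continuous at `v0`. A lung of compliance 20 ml/cmH2O and 1000 ml bag
#' reaches maximum expansion at 50 cmH2O of recoil pressure.
#'
#' @param comp a `vent_lung`, or a numeric volume in ml.
#' @param volume_ml volume above the relaxed state, ml; defaults to the
#'   compartment state.
#' @param c_lung,v0_ml,stiffening_factor used when `comp` is numeric.
#' @return gauge pressure in cmH2O.
#' @examples
#' lung_pressure(lung_compartment(20, 20), volume_ml = 400)
#' @export
lung_pressure <- function(comp, volume_ml = NULL, c_lung = NULL,
                          v0_ml = 1000, stiffening_factor = 50) {
  if (inherits(comp, "vent_lung")) {
    v <- volume_ml %||% comp$volume_ml
    c_lung <- comp$c_lung
    v0_ml <- comp$v0_ml
    stiffening_factor <- comp$stiffening_factor
  } else {
    v <- comp
    if (is.null(c_lung)) stopf("`c_lung` is required for numeric input")
  }
  if (any(v < 0)) stopf("`volume_ml` must be >= 0")
  ifelse(v <= v0_ml,
         v / c_lung,
         v0_ml / c_lung + (v - v0_ml) * stiffening_factor / c_lung)
}

#' Usable pressure excursion of a volume-limited lung
#'
#' The recoil pressure at which the lung reaches its maximum expansion,
#' `v0 / C`; ventilating above `v0/C - PEEP` of driving pressure runs into
#' the bag-stiffening regime.
#'
#' @param comp a `vent_lung`.
#' @return pressure in cmH2O.
#' @examples
#' usable_pressure(lung_compartment(20, 20, v0_ml = 1000))
#' @export
usable_pressure <- function(comp) {
  stopifnot(inherits(comp, "vent_lung"))
  comp$v0_ml / comp$c_lung
}

#' Airway flow from a driving pressure
#'
#' Solves `p_drive - p_lung = r q + k q |q|` for the signed flow `q` (l/s);
#' positive into the lung. Reduces to Ohmic division when `k = 0`; the
#' quadratic always has a unique real root of the correct sign.
#'
#' @param comp a `vent_lung`.
#' @param p_drive_cmh2o pressure at the airway opening (patient connector),
#'   cmH2O gauge.
#' @return flow in l/s (signed).
#' @examples
#' lung_flow(lung_compartment(20, 20, resistance_model = "linear"), 30)
#' @export
lung_flow <- function(comp, p_drive_cmh2o) {
  stopifnot(inherits(comp, "vent_lung"))
  d <- p_drive_cmh2o - lung_pressure(comp)
  s <- sign(d)
  d <- abs(d)
  r <- comp$r_linear
  k <- comp$k_parabolic
  q <- if (k <= 0) {
    d / r
  } else if (r <= 0) {
    sqrt(d / k)
  } else {
    (-r + sqrt(r^2 + 4 * k * d)) / (2 * k)
  }
  s * q
}

#' Integrate compartment volume over one step
#'
#' `volume <- volume + q * dt`, clamped at zero (the bag cannot be emptied
#' below its relaxed state).
#'
#' @param comp a `vent_lung`.
#' @param q_ls flow in l/s (signed, positive into the lung).
#' @param dt_s time step in s (> 0).
#' @return the updated `vent_lung`.
#' @export
update_volume <- function(comp, q_ls, dt_s) {
  stopifnot(inherits(comp, "vent_lung"))
  check_number(dt_s, "dt_s", lower = 1e-12)
  comp$volume_ml <- max(0, comp$volume_ml + q_ls * 1000 * dt_s)
  comp
}

#' Effective (instantaneous) resistance at a reference flow
#'
#' The chord resistance `dp / q` evaluated at `q_ref`, so a purely parabolic
#' orifice-plate lung can be parameterised from the rating printed at 30 or
#' 60 l/min. For a linear compartment it is the rated resistance at any flow;
#' for a parabolic one it scales linearly with the reference flow.
#'
#' @param comp a `vent_lung`.
#' @param q_ref_lmin reference flow in l/min (> 0).
#' @return resistance in cmH2O/(l/s).
#' @examples
#' effective_resistance(lung_compartment(20, 20), 30)
#' @export
effective_resistance <- function(comp, q_ref_lmin = 60) {
  stopifnot(inherits(comp, "vent_lung"))
  check_number(q_ref_lmin, "q_ref_lmin", lower = 1e-9)
  q <- q_ref_lmin / 60
  (comp$r_linear * q + comp$k_parabolic * q^2) / q
}
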