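# Pneumatics: valves, calibrated flow pathways, gas supplies and the
# ideal-gas mixing reservoir (the upstream half of the circuit).

#' Gas supply
#'
#' A constant-pressure source feeding the mixing reservoir through one of the
#' inlet valves. Hospital gas lines are 4 bar gauge; a portable oxygen
#' concentrator provides about 1.3 bar gauge.
#'
#' @param pressure_bar_gauge supply pressure in bar gauge (>= 0).
#' @param o2_fraction oxygen mole fraction of the supplied gas, in \[0, 1\]
#'   (0.21 for air, 1 for cylinder oxygen).
#' @param label text label.
#' @return an object of class `vent_gas_supply`.
#' @examples
#' gas_supply(4, 1, "O2 line")
#' @export
gas_supply <- function(pressure_bar_gauge, o2_fraction, label = "") {
  check_number(pressure_bar_gauge, "pressure_bar_gauge", lower = 0)
  check_number(o2_fraction, "o2_fraction", lower = 0, upper = 1)
  structure(
    list(
      pressure_abs_pa = P_ATM_PA + bar_to_pa(pressure_bar_gauge),
      pressure_bar_gauge = pressure_bar_gauge,
      o2_fraction = o2_fraction,
      label = label
    ),
    class = "vent_gas_supply"
  )
}

#' @export
print.vent_gas_supply <- function(x, ...) {
  cat(sprintf(
    "<gas supply%s: %.2f bar gauge, FO2 %.2f>\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    x$pressure_bar_gauge, x$o2_fraction
  ))
  invisible(x)
}

#' On-off solenoid valve specification
#'
#' @param kv flow coefficient in m3/h/bar^0.5 (> 0), the water rating from
#'   the valve data sheet.
#' @param role circuit role: `"A"` (oxygen inlet), `"B"` (air inlet),
#'   `"C"` (inhalation), `"D"` (exhalation).
#' @param rest_state `"normally_closed"` or `"normally_open"`. Inlet and
#'   inhalation valves are normally closed so a power failure isolates the
#'   patient from the supply; the exhalation valve defaults to normally open
#'   so an unpowered patient can breathe room air.
#' @return an object of class `vent_valve`.
#' @examples
#' valve_spec(0.17, "C")
#' @export
valve_spec <- function(kv, role = c("A", "B", "C", "D"), rest_state = NULL) {
  check_number(kv, "kv", lower = 1e-9)
  role <- match.arg(role)
  if (is.null(rest_state)) {
    rest_state <- if (role == "D") "normally_open" else "normally_closed"
  }
  rest_state <- match.arg(rest_state, c("normally_closed", "normally_open"))
  structure(list(kv = kv, role = role, rest_state = rest_state),
            class = "vent_valve")
}

#' Calibrated power-law flow pathway
#'
#' Each pneumatic pathway (a valve lumped with its connectors, filters and
#' manifolds) is characterised by `q = a * dp^n`. In the calibration
#' convention used throughout the package, `q` is in l/min and `dp` in mbar,
#' with `a = 13.1 * kv` for a pathway dominated by a valve of flow
#' coefficient `kv` and `n = 0.5` for orifice-dominated pathways.
#'
#' @param a power-law coefficient (> 0), flow units per pressure-drop^n.
#' @param n power-law exponent in (0, 1].
#' @param label direction/pathway label.
#' @return an object of class `vent_flow_path`.
#' @examples
#' flow_path(a_from_kv(0.17), 0.5, "inhalation")
#' @export
flow_path <- function(a, n = 0.5, label = "") {
  check_number(a, "a", lower = 1e-12)
  check_number(n, "n", lower = 1e-6, upper = 1)
  structure(list(a = a, n = n, label = label), class = "vent_flow_path")
}

#' Pathway coefficient from a valve flow coefficient
#'
#' The calibrated power-law coefficient of a pathway scales linearly with the
#' flow coefficient of its valve, `a = 13.1 * kv` (q in l/min, dp in mbar);
#' the exponent is insensitive to the valve size.
#'
#' @param kv flow coefficient in m3/h/bar^0.5 (> 0).
#' @param slope calibration slope, default 13.1.
#' @return power-law coefficient `a` in l/min/mbar^n.
#' @examples
#' a_from_kv(0.17)
#' @export
a_from_kv <- function(kv, slope = 13.1) {
  if (any(kv <= 0)) stopf("`kv` must be > 0")
  slope * kv
}

#' Orifice (valve data-sheet) flow
#'
#' The defining relation of the flow coefficient: a valve of coefficient `kv`
#' passes `kv * sqrt(dp)` m3/h of water at a pressure drop of `dp` bar. Used
#' for parameterisation and cross-checks; simulated pathways use the
#' calibrated power law ([path_flow()]).
#'
#' @param kv flow coefficient in m3/h/bar^0.5 (> 0).
#' @param dp_bar pressure drop in bar (>= 0).
#' @return volumetric flow in m3/h.
#' @examples
#' orifice_flow(0.17, 0.25)
#' @export
orifice_flow <- function(kv, dp_bar) {
  if (any(kv <= 0)) stopf("`kv` must be > 0")
  if (any(dp_bar < 0)) stopf("`dp_bar` must be >= 0; orient the pressure drop")
  kv * sqrt(dp_bar)
}

#' Power-law pathway flow
#'
#' `q = a * dp^n`, zero at zero drop and strictly increasing in the drop.
#' Units follow the caller's convention for `a` and `dp` (the engine uses
#' l/min and mbar).
#'
#' @param path a [flow_path()], or a numeric coefficient `a`.
#' @param dp pressure drop (>= 0) in the units `a` was calibrated with.
#' @param n exponent, used only when `path` is numeric.
#' @return volumetric flow.
#' @examples
#' path_flow(flow_path(2, 0.5), 4)
#' path_flow(a_from_kv(0.17), 1000) # l/min at a 1 bar (1000 mbar) drop
#' @export
path_flow <- function(path, dp, n = 0.5) {
  if (inherits(path, "vent_flow_path")) {
    a <- path$a
    n <- path$n
  } else {
    a <- path
    check_number(n, "n", lower = 1e-6, upper = 1)
  }
  if (any(dp < 0)) stopf("`dp` must be >= 0; orient the pressure drop")
  a * dp^n
}

#' Mixing reservoir
#'
#' Fixed-volume (default 2 l) isothermal ideal-gas reservoir in which the
#' oxygen/air mixture for the next breath is prepared. Its pneumatic
#' compliance is `C_res = V_res / p_res` and therefore falls as the pressure
#' rises.
#'
#' @param volume_l reservoir volume in litres (> 0).
#' @param pressure_bar_gauge initial pressure in bar gauge (>= 0).
#' @param o2_fraction oxygen mole fraction in \[0, 1\].
#' @param temperature_k temperature (isothermal), default 293.15 K.
#' @return an object of class `vent_reservoir`.
#' @examples
#' reservoir()
#' @export
reservoir <- function(volume_l = 2, pressure_bar_gauge = 0,
                      o2_fraction = 0.21, temperature_k = 293.15) {
  check_number(volume_l, "volume_l", lower = 1e-6)
  check_number(pressure_bar_gauge, "pressure_bar_gauge", lower = 0)
  check_number(o2_fraction, "o2_fraction", lower = 0, upper = 1)
  structure(
    list(
      volume_l = volume_l,
      pressure_abs_pa = P_ATM_PA + bar_to_pa(pressure_bar_gauge),
      o2_fraction = o2_fraction,
      temperature_k = temperature_k,
      relief_events = 0L
    ),
    class = "vent_reservoir"
  )
}

#' @export
print.vent_reservoir <- function(x, ...) {
  cat(sprintf(
    "<reservoir: %.2f l, %.3f bar gauge, FO2 %.3f, C_res %.2f ml/mbar>\n",
    x$volume_l, pa_to_bar(x$pressure_abs_pa - P_ATM_PA), x$o2_fraction,
    reservoir_compliance(x)
  ))
  invisible(x)
}

#' Reservoir pneumatic compliance
#'
#' `C_res = V_res / p_res` expressed in ml of atmospheric-equivalent gas per
#' mbar of pressure change; always positive and decreasing in pressure.
#'
#' @param res a [reservoir()].
#' @return compliance in ml/mbar.
#' @export
reservoir_compliance <- function(res) {
  1000 * res$volume_l / res$pressure_abs_pa * MBAR_PA
}

#' Charge the reservoir from a gas supply
#'
#' Isothermal ideal-gas bookkeeping for one time step: adding an
#' atmospheric-equivalent volume `inflow_ls * dt_s` (litres at 1 atm) raises
#' the pressure by `P_atm * dV / V_res` and updates the oxygen fraction as a
#' mole-weighted mixture of old contents and supply gas. If the result would
#' exceed `relief_bar_gauge` the mechanical relief valve vents the excess:
#' the pressure is clamped and a relief event is counted.
#'
#' @param res a [reservoir()].
#' @param inflow_ls inflow in atmospheric-equivalent l/s (>= 0).
#' @param supply a [gas_supply()] (its `o2_fraction` enters the mole balance).
#' @param dt_s time step in seconds (> 0).
#' @param relief_bar_gauge mechanical relief ceiling, default 1 bar gauge.
#' @return the updated `vent_reservoir`.
#' @examples
#' r <- reservoir(2, 0, o2_fraction = 0.21)
#' reservoir_charge_step(r, inflow_ls = 0.2, gas_supply(4, 1), dt_s = 1)
#' @export
reservoir_charge_step <- function(res, inflow_ls, supply, dt_s,
                                  relief_bar_gauge = 1) {
  check_number(inflow_ls, "inflow_ls", lower = 0)
  check_number(dt_s, "dt_s", lower = 1e-12)
  dv_l <- inflow_ls * dt_s
  dp <- P_ATM_PA * dv_l / res$volume_l
  p_new <- res$pressure_abs_pa + dp
  f_new <- (res$o2_fraction * res$pressure_abs_pa + supply$o2_fraction * dp) /
    p_new
  ceiling_pa <- P_ATM_PA + bar_to_pa(relief_bar_gauge)
  if (p_new > ceiling_pa) {
    warning("reservoir relief valve opened: pressure clamped at ceiling",
            call. = FALSE)
    p_new <- ceiling_pa
    res$relief_events <- res$relief_events + 1L
  }
  res$pressure_abs_pa <- p_new
  res$o2_fraction <- f_new
  res
}

#' Discharge the reservoir
#'
#' Removes an atmospheric-equivalent volume `outflow_ls * dt_s`; the pressure
#' falls per the ideal gas law and the composition is unchanged (well-mixed).
#' The pressure never falls below atmospheric: a demanded outflow exceeding
#' the available over-pressure is truncated with a warning.
#'
#' @param res a [reservoir()].
#' @param outflow_ls outflow in atmospheric-equivalent l/s (>= 0).
#' @param dt_s time step in seconds (> 0).
#' @return the updated `vent_reservoir`.
#' @export
reservoir_discharge_step <- function(res, outflow_ls, dt_s) {
  check_number(outflow_ls, "outflow_ls", lower = 0)
  check_number(dt_s, "dt_s", lower = 1e-12)
  dp <- P_ATM_PA * outflow_ls * dt_s / res$volume_l
  avail <- res$pressure_abs_pa - P_ATM_PA
  if (dp > avail) {
    warning("reservoir at atmospheric pressure: outflow truncated",
            call. = FALSE)
    dp <- avail
  }
  res$pressure_abs_pa <- res$pressure_abs_pa - dp
  res
}

#' Patient-connector pressure during inhalation
#'
#' During inhalation the gas crosses the internal pathway between the system
#' pressure sensor and the patient connector, dropping
#' `p_conn = p_sys - (q_I / (13.1 kv_s))^(1/n)` mbar in the calibration
#' convention (q in l/min). At zero flow the two pressures are equal.
#'
#' @param p_sys_cmh2o system (manifold) pressure, cmH2O gauge.
#' @param q_i_lmin inspiratory flow in l/min (>= 0).
#' @param kv_s flow coefficient of the connector pathway, m3/h/bar^0.5.
#' @param n pathway exponent, default 0.5.
#' @return connector pressure in cmH2O gauge, `<= p_sys_cmh2o` with equality
#'   iff the flow is zero.
#' @examples
#' connector_pressure(30, 30, kv_s = 1)
#' @export
connector_pressure <- function(p_sys_cmh2o, q_i_lmin, kv_s = 1, n = 0.5) {
  if (any(q_i_lmin < 0)) stopf("`q_i_lmin` must be >= 0")
  drop_mbar <- (q_i_lmin / a_from_kv(kv_s))^(1 / n)
  p_sys_cmh2o - drop_mbar * MBAR_PA / CMH2O_PA
}

#' Ventilator pneumatic circuit
#'
#' Bundles the four on-off valves, the connector pathway, the two gas
#' supplies, the mixing reservoir and the relief set-points into the
#' configuration consumed by [simulate_ventilation()]. Defaults are the
#' prototype values: Kv_C = 0.17 (the 2.4 mm valve), Kv_A = Kv_B = 0.12 and
#' Kv_D = 0.70 chosen from the 262-series range for the 1.2 mm and 5.6 mm
#' valves, 4 bar gauge air and oxygen supplies, and a 2 l reservoir.
#'
#' @param kv_a,kv_b,kv_c,kv_d valve flow coefficients, m3/h/bar^0.5.
#' @param kv_s connector-pathway flow coefficient.
#' @param n_inhale,n_exhale power-law exponents of the inhalation-side and
#'   exhalation pathways.
#' @param supply_air,supply_o2 [gas_supply()] objects.
#' @param reservoir_volume_l reservoir volume, litres.
#' @param relief_reservoir_bar_gauge reservoir mechanical-relief ceiling.
#' @param relief_patient_cmh2o patient-side relief ceiling.
#' @param a_slope calibration slope of [a_from_kv()].
#' @return an object of class `vent_circuit`.
#' @examples
#' ventilator_circuit()
#' @export
ventilator_circuit <- function(kv_a = 0.12, kv_b = 0.12, kv_c = 0.17,
                               kv_d = 0.70, kv_s = 1.0,
                               n_inhale = 0.5, n_exhale = 0.5,
                               supply_air = gas_supply(4, 0.21, "air"),
                               supply_o2 = gas_supply(4, 1.0, "oxygen"),
                               reservoir_volume_l = 2,
                               relief_reservoir_bar_gauge = 1.0,
                               relief_patient_cmh2o = 60,
                               a_slope = 13.1) {
  for (nm in c("kv_a", "kv_b", "kv_c", "kv_d", "kv_s")) {
    check_number(get(nm), nm, lower = 1e-6)
  }
  check_number(n_inhale, "n_inhale", lower = 1e-6, upper = 1)
  check_number(n_exhale, "n_exhale", lower = 1e-6, upper = 1)
  check_number(reservoir_volume_l, "reservoir_volume_l", lower = 0.05)
  check_number(relief_reservoir_bar_gauge, "relief_reservoir_bar_gauge",
               lower = 0.05)
  check_number(relief_patient_cmh2o, "relief_patient_cmh2o", lower = 5)
  stopifnot(inherits(supply_air, "vent_gas_supply"),
            inherits(supply_o2, "vent_gas_supply"))
  structure(
    list(
      valves = list(
        A = valve_spec(kv_a, "A"), B = valve_spec(kv_b, "B"),
        C = valve_spec(kv_c, "C"), D = valve_spec(kv_d, "D")
      ),
      kv_s = kv_s,
      n_inhale = n_inhale, n_exhale = n_exhale,
      supply_air = supply_air, supply_o2 = supply_o2,
      reservoir_volume_l = reservoir_volume_l,
      relief_reservoir_bar_gauge = relief_reservoir_bar_gauge,
      relief_patient_cmh2o = relief_patient_cmh2o,
      a_slope = a_slope
    ),
    class = "vent_circuit"
  )
}

#' @export
print.vent_circuit <- function(x, ...) {
  kv <- vapply(x$valves, function(v) v$kv, numeric(1))
  cat(sprintf(
    "<ventilator circuit: Kv A/B/C/D = %.2f/%.2f/%.2f/%.2f, Kv_s = %.2f>\n",
    kv["A"], kv["B"], kv["C"], kv["D"], x$kv_s
  ))
  cat(sprintf("  air %.2f bar gauge, O2 %.2f bar gauge, reservoir %.1f l\n",
              x$supply_air$pressure_bar_gauge,
              x$supply_o2$pressure_bar_gauge, x$reservoir_volume_l))
  invisible(x)
}
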