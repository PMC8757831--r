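# Six-phase PRVC timing controller: clinician settings, breath planning
# (reservoir pressure target + oxygen/air mixing split), sensor-only
# estimators and the per-tick valve scheduler.
#
# Phases within one breath:
#   1  Valve C open, reservoir gas flows to the patient; C closes once the
#      set tidal volume has been delivered (integrated from the two pressure
#      sensors, no flow sensor).
#   2  all valves closed until the inspiratory time T_in.
#   3  at T_in, Valve D opens (exhalation) and Valve A opens (oxygen charge).
#   4  A -> B handover after the planned oxygen share of the pressure rise.
#   5  B closes when the reservoir reaches its target pressure.
#   6  D closes when the estimated lung pressure reaches PEEP; pressure held
#      until the next breath starts at 60/RR.
# The exhalation (D) and charging (A/B) tracks run independently; the
# reported phase label is derived from their joint state.

#' Parse an I:E ratio string
#'
#' @param ie ratio string `"1:E"` with E >= 1 (by convention I = 1), or a
#'   single number E.
#' @return the expiratory fraction E.
#' @examples
#' parse_ie("1:2")
#' @export
parse_ie <- function(ie) {
  if (is.numeric(ie)) {
    e <- ie
  } else {
    m <- regmatches(ie, regexec("^\\s*1\\s*:\\s*([0-9.]+)\\s*$", ie))[[1]]
    if (length(m) != 2L) stopf("malformed I:E ratio '%s' (want '1:E')", ie)
    e <- as.numeric(m[2])
  }
  check_number(e, "E", lower = 1)
  e
}

#' Clinician ventilation settings
#'
#' The PRVC inputs: tidal volume, respiratory rate, PEEP, I:E ratio and
#' FiO2, plus the peak-pressure alarm threshold. Derived timing:
#' `T_in = 60/RR * 1/(1+E)`, `T_ex = 60/RR * E/(1+E)` and the mean
#' inspiratory flow `q_bar = V_T / T_in`.
#'
#' @param vt_ml tidal volume in ml, in \[200, 800\].
#' @param rr_bpm respiratory rate in breaths/min, in \[10, 35\].
#' @param peep_cmh2o PEEP in cmH2O gauge (>= 0).
#' @param ie I:E ratio string `"1:E"` (E >= 1) or the number E.
#' @param fio2 target inspired oxygen fraction in \[0.21, 1\].
#' @param alarm_pip_cmh2o peak-pressure alarm, default 45 cmH2O; when the
#'   estimated connector pressure exceeds it the controller closes Valve C
#'   and opens Valve D.
#' @return an object of class `vent_settings`.
#' @examples
#' vent_settings(400, 15, 5, "1:3", 0.30)
#' @export
vent_settings <- function(vt_ml, rr_bpm, peep_cmh2o, ie = "1:2",
                          fio2 = 0.21, alarm_pip_cmh2o = 45) {
  check_number(vt_ml, "vt_ml", lower = 200, upper = 800)
  check_number(rr_bpm, "rr_bpm", lower = 10, upper = 35)
  check_number(peep_cmh2o, "peep_cmh2o", lower = 0, upper = 30)
  check_number(fio2, "fio2", lower = 0.21, upper = 1)
  check_number(alarm_pip_cmh2o, "alarm_pip_cmh2o", lower = 10)
  e <- parse_ie(ie)
  period <- 60 / rr_bpm
  t_in <- period / (1 + e)
  structure(
    list(
      vt_ml = vt_ml, rr_bpm = rr_bpm, peep_cmh2o = peep_cmh2o,
      e_ratio = e, fio2 = fio2, alarm_pip_cmh2o = alarm_pip_cmh2o,
      t_in_s = t_in, t_ex_s = period - t_in,
      q_bar_ls = vt_ml / 1000 / t_in
    ),
    class = "vent_settings"
  )
}

#' @export
print.vent_settings <- function(x, ...) {
  cat(sprintf(
    "<settings: VT %g ml, RR %g bpm, PEEP %g cmH2O, I:E 1:%g, FiO2 %g%%>\n",
    x$vt_ml, x$rr_bpm, x$peep_cmh2o, x$e_ratio, 100 * x$fio2
  ))
  cat(sprintf("  T_in %.3f s, T_ex %.3f s, mean inspiratory flow %.2f l/s\n",
              x$t_in_s, x$t_ex_s, x$q_bar_ls))
  invisible(x)
}

#' Peak inspiratory pressure estimate for an ideal lung
#'
#' For a constant-compliance, constant-resistance lung the expected peak
#' pressure is `PiP = PEEP + V_T/C + R_air * q_bar` with
#' `q_bar = V_T / T_in` (gauge cmH2O). Used to screen out parameter
#' combinations that would over-pressurise the lung and as the alarm
#' reference.
#'
#' @param settings a [vent_settings()].
#' @param c_lung compliance in ml/cmH2O (> 0).
#' @param r_air airway resistance in cmH2O/(l/s).
#' @return estimated PiP in cmH2O gauge.
#' @examples
#' estimate_pip(vent_settings(400, 15, 5, "1:3"), c_lung = 20, r_air = 20)
#' @export
estimate_pip <- function(settings, c_lung, r_air) {
  stopifnot(inherits(settings, "vent_settings"))
  check_number(c_lung, "c_lung", lower = 1e-6)
  settings$peep_cmh2o + settings$vt_ml / c_lung + r_air * settings$q_bar_ls
}

#' Screen sweep cases by expected peak pressure
#'
#' Keeps the rows whose [estimate_pip()] against the given lung does not
#' exceed `limit_cmh2o` (default 45), preserving order.
#'
#' @param cases a data frame with columns `vt_ml`, `rr_bpm`, `peep_cmh2o` and
#'   `ie` (string) or `e_ratio` (numeric), as produced by
#'   [parametric_sweep_cases()].
#' @param lung a `vent_lung` (its rated resistance enters the estimate).
#' @param limit_cmh2o screening limit in cmH2O.
#' @return the kept subset of `cases`, as a tibble with a `pip_est` column.
#' @export
screen_sweep_cases <- function(cases, lung, limit_cmh2o = 45) {
  stopifnot(is.data.frame(cases))
  lung <- if (inherits(lung, "vent_lung")) lung else parse_lung(lung)
  check_number(limit_cmh2o, "limit_cmh2o", lower = 0)
  e <- if ("e_ratio" %in% names(cases)) cases$e_ratio else
    vapply(cases$ie, parse_ie, numeric(1))
  t_in <- 60 / cases$rr_bpm / (1 + e)
  q_bar <- cases$vt_ml / 1000 / t_in
  pip <- cases$peep_cmh2o + cases$vt_ml / lung$c_lung + lung$r_rated * q_bar
  out <- tibble::as_tibble(cases)
  out$pip_est <- pip
  out[pip <= limit_cmh2o, , drop = FALSE]
}

#' Plan the next breath
#'
#' PRVC breath planning. The reservoir-pressure target is the expected
#' end-of-delivery system pressure (the [estimate_pip()] of the current
#' compliance/resistance estimates) plus the ideal-gas depletion
#' `P_atm * V_T / V_res` plus a margin, corrected breath-to-breath by the
#' accumulated adaptation term `lambda * (V_T - V_T,delivered) * P_atm/V_res`
#' and clamped at the reservoir relief ceiling. The oxygen/air pressure
#' shares solve the one-breath mole balance so the steady-state delivered
#' fraction equals the FiO2 target:
#' `dp_O2 = (F_t p1 - F_prev p0 - 0.21 (p1 - p0)) / (1 - 0.21)`,
#' clamped to `[0, p1 - p0]` (an unreachable FiO2 converges over breaths).
#'
#' @param settings a [vent_settings()].
#' @param res a [reservoir()] in its end-of-delivery state.
#' @param last_metrics optional one-row data frame (or list) of the previous
#'   breath's metrics with `c_est`, `r_est` and `v_t_delivered` fields, as
#'   produced by [breath_metrics()].
#' @param margin_mbar fixed margin on the target, default 20 mbar.
#' @param lambda adaptation gain, default 0.7.
#' @param correction_pa accumulated adaptation from previous breaths, Pa.
#' @param relief_bar_gauge reservoir relief ceiling.
#' @param c_est0,r_est0 estimates used before any breath has been measured.
#' @param o2_supply_fraction oxygen fraction of the O2 supply.
#' @return a list with `p_res_target_pa` (absolute), `o2_share_pa`,
#'   `air_share_pa`, `correction_pa`, `pip_est_cmh2o` and `fio2_clamped`.
#' @examples
#' plan_breath(vent_settings(400, 15, 5, "1:3", 0.6), reservoir())
#' @export
plan_breath <- function(settings, res, last_metrics = NULL,
                        margin_mbar = 20, lambda = 0.7, correction_pa = 0,
                        relief_bar_gauge = 1, c_est0 = 30, r_est0 = 20,
                        o2_supply_fraction = 1) {
  stopifnot(inherits(settings, "vent_settings"),
            inherits(res, "vent_reservoir"))
  c_est <- c_est0
  r_est <- r_est0
  if (!is.null(last_metrics)) {
    if (!is.na(last_metrics$c_est %||% NA)) c_est <- last_metrics$c_est
    if (!is.na(last_metrics$r_est %||% NA)) r_est <- last_metrics$r_est
  }
  pip_est <- estimate_pip(settings, c_est, r_est)
  base <- P_ATM_PA + cmh2o_to_pa(pip_est) +
    P_ATM_PA * (settings$vt_ml / 1000) / res$volume_l +
    margin_mbar * MBAR_PA
  if (!is.null(last_metrics)) {
    shortfall_l <- (settings$vt_ml - last_metrics$v_t_delivered) / 1000
    step_pa <- lambda * shortfall_l * P_ATM_PA / res$volume_l
    # each adaptation step clipped to 20% of the current gauge target
    cap <- 0.2 * max(base + correction_pa - P_ATM_PA, 5000)
    correction_pa <- correction_pa + max(-cap, min(cap, step_pa))
  }
  target <- base + correction_pa
  target <- min(target, P_ATM_PA + bar_to_pa(relief_bar_gauge))
  target <- max(target, res$pressure_abs_pa)
  p0 <- res$pressure_abs_pa
  rise <- target - p0
  f_air <- 0.21
  dpo2 <- (settings$fio2 * target - res$o2_fraction * p0 - f_air * rise) /
    (o2_supply_fraction - f_air)
  clamped <- dpo2 < 0 || dpo2 > rise
  dpo2 <- max(0, min(rise, dpo2))
  list(
    p_res_target_pa = target,
    o2_share_pa = dpo2,
    air_share_pa = rise - dpo2,
    correction_pa = correction_pa,
    pip_est_cmh2o = pip_est,
    fio2_clamped = clamped
  )
}

#' Estimate airway resistance from the exhalation onset
#'
#' At the start of exhalation the lung pressure still equals the plateau
#' pressure, so `R_air ~ (p_plat - p_sys) / q_E` at the first sample with
#' appreciable exhaled flow. Optionally refined by a zero-intercept least
#' squares of `(p_plat - p_sys)` on `q_E` over the first `refine_ms`
#' milliseconds. Returns the previous estimate (flagged stale) when the flow
#' never rises above the noise floor.
#'
#' @param window data frame of early-exhalation samples with columns `time`
#'   (s), `p_sys` (cmH2O) and `q_e` (l/s).
#' @param p_plat plateau pressure at end-inspiration, cmH2O.
#' @param previous previous estimate, returned when the window is unusable.
#' @param refine_ms least-squares refinement window (0 disables), default 0.
#' @param q_floor_ls flow noise floor, l/s.
#' @param ceiling upper bound on the estimate, cmH2O/(l/s).
#' @return resistance in cmH2O/(l/s) with attribute `stale`.
#' @export
estimate_r_air <- function(window, p_plat, previous = NA_real_,
                           refine_ms = 0, q_floor_ls = 0.01, ceiling = 300) {
  stopifnot(is.data.frame(window), all(c("p_sys", "q_e") %in% names(window)))
  ok <- which(window$q_e > q_floor_ls)
  if (!length(ok)) {
    return(structure(previous, stale = TRUE))
  }
  i0 <- ok[1]
  est <- (p_plat - window$p_sys[i0]) / window$q_e[i0]
  if (refine_ms > 0 && "time" %in% names(window)) {
    t0 <- window$time[i0]
    sel <- window$q_e > q_floor_ls & window$time <= t0 + refine_ms / 1000
    if (sum(sel) >= 2) {
      fit <- lm(I(p_plat - p_sys) ~ 0 + q_e, data = window[sel, ])
      est <- unname(coef(fit)[1])
    }
  }
  structure(min(max(est, 0), ceiling), stale = FALSE)
}

#' Estimate lung pressure during exhalation
#'
#' During exhalation no flow crosses the internal connector pathway, so the
#' measured system pressure equals the connector pressure and
#' `p_lung = p_sys + R_air * q_E`. With the parabolic (orifice-plate)
#' variant the drop is `k q_E^2` where `k = r_air / q_ref_ls` is anchored at
#' the flow `q_ref_ls` at which `r_air` was estimated, so the drop is exact
#' for an orifice-plate lung rather than over-predicted at decaying flows.
#'
#' @param p_sys_cmh2o measured system pressure, cmH2O gauge.
#' @param q_e_ls exhaled flow, l/s (>= 0).
#' @param r_air resistance estimate, cmH2O/(l/s).
#' @param model `"parabolic"` (default) or `"linear"`.
#' @param q_ref_ls flow at which `r_air` was estimated (parabolic anchor).
#' @return estimated lung pressure, cmH2O gauge (never below `p_sys_cmh2o`).
#' @examples
#' estimate_p_lung_exhale(8, 0.25, 20, model = "linear")
#' @export
estimate_p_lung_exhale <- function(p_sys_cmh2o, q_e_ls, r_air,
                                   model = c("parabolic", "linear"),
                                   q_ref_ls = 1) {
  if (any(q_e_ls < 0)) stopf("`q_e_ls` must be >= 0")
  model <- match.arg(model)
  drop <- switch(model,
    linear = r_air * q_e_ls,
    parabolic = (r_air / q_ref_ls) * q_e_ls^2
  )
  p_sys_cmh2o + pmax(drop, 0)
}

#' Initial controller state
#'
#' State record consumed by [controller_tick()]; one per breath.
#'
#' @param t_start breath start time, s.
#' @param plan the [plan_breath()] result for this breath.
#' @param k_est parabolic resistance coefficient estimate, cmH2O/(l/s)^2.
#' @return a list of class `vent_ctrl_state`.
#' @export
controller_state <- function(t_start = 0, plan = NULL, k_est = 20) {
  structure(
    list(
      t_start = t_start, plan = plan, k_est = k_est,
      c_open = TRUE, d_open = FALSE, a_open = FALSE, b_open = FALSE,
      exhal_started = FALSE, delivered_ml = 0,
      p_plat_cmh2o = NA_real_, charge_p0_pa = NA_real_,
      onset_done = FALSE, alarm = FALSE, short = FALSE,
      t_c_closed = NA_real_, t_d_opened = NA_real_, t_d_closed = NA_real_
    ),
    class = "vent_ctrl_state"
  )
}

#' One controller tick
#'
#' Reference implementation of the valve scheduler, executed once per control
#' period. Phase 1: Valve C open until the integrated delivered volume
#' reaches V_T (hard cutoff at T_in). Phase 3 starts at T_in: Valve D opens
#' and the charging track opens Valve A, handing over to B after the planned
#' oxygen share of the reservoir pressure rise, closing B at the target.
#' Valve D closes when the estimated lung pressure reaches
#' PEEP + `peep_margin`. If the estimated connector pressure exceeds the
#' alarm limit the controller enters the safe state (C closed, D open).
#'
#' The compiled simulation engine embeds this same scheduler; this function
#' exists as the testable specification of a single tick.
#'
#' @param state a [controller_state()].
#' @param sensors list with `p_res_pa` (absolute), `p_sys_cmh2o` (gauge) and
#'   optionally `o2` (delivered fraction).
#' @param t current time, s.
#' @param settings a [vent_settings()].
#' @param circuit a [ventilator_circuit()].
#' @param control_period_s tick period, default 0.005 s.
#' @param peep_margin_cmh2o close-D margin above PEEP, default 1.
#' @return list with `commands` (named logical A/B/C/D) and the new `state`.
#' @export
controller_tick <- function(state, sensors, t, settings, circuit,
                            control_period_s = 0.005,
                            peep_margin_cmh2o = 1) {
  stopifnot(inherits(state, "vent_ctrl_state"),
            inherits(settings, "vent_settings"),
            inherits(circuit, "vent_circuit"))
  tb <- t - state$t_start
  a_c <- a_from_kv(circuit$valves$C$kv, circuit$a_slope)
  a_d <- a_from_kv(circuit$valves$D$kv, circuit$a_slope)
  a_s <- a_from_kv(circuit$kv_s, circuit$a_slope)
  p_sys_pa <- cmh2o_to_pa(sensors$p_sys_cmh2o)

  if (state$c_open) {
    dp_mbar <- max(0, sensors$p_res_pa - P_ATM_PA - p_sys_pa) / MBAR_PA
    q_lmin <- path_flow(a_c, dp_mbar, circuit$n_inhale)
    state$delivered_ml <- state$delivered_ml +
      q_lmin / 60 * 1000 * control_period_s
    p_conn_est <- connector_pressure(sensors$p_sys_cmh2o, q_lmin,
                                     circuit$kv_s, circuit$n_inhale)
    if (p_conn_est > settings$alarm_pip_cmh2o) {
      state$alarm <- TRUE
      state$c_open <- FALSE
      state$d_open <- TRUE
      state$exhal_started <- TRUE
      state$t_c_closed <- t
      state$t_d_opened <- t
    } else if (state$delivered_ml >= settings$vt_ml) {
      state$c_open <- FALSE
      state$t_c_closed <- t
    } else if (tb >= settings$t_in_s - 1e-9) {
      state$c_open <- FALSE
      state$short <- TRUE
      state$t_c_closed <- t
    }
  }

  if (!state$exhal_started && !state$c_open && tb < settings$t_in_s) {
    # phase 2: remember the equilibrated plateau pressure
    state$p_plat_cmh2o <- sensors$p_sys_cmh2o
  }

  if (!state$exhal_started && tb >= settings$t_in_s - 1e-9) {
    state$exhal_started <- TRUE
    state$d_open <- TRUE
    state$t_d_opened <- t
    state$charge_p0_pa <- sensors$p_res_pa
    if (!is.null(state$plan)) {
      if (state$plan$o2_share_pa > 50) {
        state$a_open <- TRUE
      } else if (state$plan$p_res_target_pa - sensors$p_res_pa > 50) {
        state$b_open <- TRUE
      }
    }
  }

  if (state$exhal_started && state$d_open) {
    dp_mbar <- max(0, p_sys_pa) / MBAR_PA
    q_e_ls <- path_flow(a_d, dp_mbar, circuit$n_exhale) / 60
    if (!state$onset_done && q_e_ls > 0.01) {
      if (!is.na(state$p_plat_cmh2o)) {
        state$k_est <- max(0.5, min(500,
          (state$p_plat_cmh2o - sensors$p_sys_cmh2o) / q_e_ls^2))
      }
      state$onset_done <- TRUE
    }
    p_lung_est <- sensors$p_sys_cmh2o +
      if (state$onset_done) state$k_est * q_e_ls^2 else 0
    if (state$onset_done &&
        p_lung_est <= settings$peep_cmh2o + peep_margin_cmh2o) {
      state$d_open <- FALSE
      state$t_d_closed <- t
    }
  }

  if (state$a_open &&
      sensors$p_res_pa >= state$charge_p0_pa + state$plan$o2_share_pa) {
    state$a_open <- FALSE
    if (state$plan$p_res_target_pa - sensors$p_res_pa > 50) {
      state$b_open <- TRUE
    }
  } else if (state$b_open &&
             sensors$p_res_pa >= state$plan$p_res_target_pa) {
    state$b_open <- FALSE
  }

  list(
    commands = c(A = state$a_open, B = state$b_open,
                 C = state$c_open, D = state$d_open),
    state = state
  )
}

#' Fig.-style phase label from the joint valve state
#'
#' @param c_open,d_open,a_open,b_open valve states.
#' @param before_t_in is the breath clock still before T_in?
#' @return integer phase 1-6.
#' @keywords internal
phase_label <- function(c_open, d_open, a_open, b_open, before_t_in) {
  dplyr::case_when(
    c_open ~ 1L,
    before_t_in ~ 2L,
    a_open ~ 3L,
    b_open ~ 4L,
    d_open ~ 5L,
    TRUE ~ 6L
  )
}
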