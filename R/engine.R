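# Simulation engine wrappers around the compiled fixed-step core.

#' Simulation configuration
#'
#' Fixed integration step, control period, trace sample rate and optional
#' seeded sensor noise. Defaults: dt = 0.5 ms, control period 5 ms (the
#' prototype's LabVIEW loop ran nearer 20 ms; both must meet the ISO bands),
#' 200 Hz sampling.
#'
#' @param dt_s integration step, s.
#' @param control_period_s controller tick period, s (>= dt).
#' @param sample_rate_hz trace sampling rate, Hz.
#' @param n_breaths number of breaths to simulate.
#' @param sensor_noise optional list with `pressure_cmh2o` and `o2` standard
#'   deviations; `NULL` (default) disables noise.
#' @param seed RNG seed applied before the run when noise is enabled.
#' @param peep_margin_cmh2o controller margin above PEEP at which Valve D is
#'   closed (keeps achieved PEEP from undershooting the target).
#' @param margin_mbar fixed margin on the reservoir pressure target.
#' @param lambda breath-to-breath adaptation gain.
#' @param c_est0 compliance estimate (ml/cmH2O) used before the first breath
#'   has been measured.
#' @param rk_est0 initial airway-resistance estimate: a parabolic
#'   coefficient in cmH2O/(l/s)^2 when `est_parabolic`, else cmH2O/(l/s).
#' @param est_parabolic should the controller's exhalation estimator use the
#'   parabolic (orifice-plate) drop model? Default TRUE.
#' @param precharge start the reservoir pre-charged at the first breath's
#'   target (the device charges before ventilation starts). Default TRUE.
#' @return an object of class `vent_sim_config`.
#' @export
sim_config <- function(dt_s = 5e-4, control_period_s = 5e-3,
                       sample_rate_hz = 200, n_breaths = 20,
                       sensor_noise = NULL, seed = NULL,
                       peep_margin_cmh2o = 1, margin_mbar = 20,
                       lambda = 0.7, c_est0 = 30, rk_est0 = 20,
                       est_parabolic = TRUE, precharge = TRUE) {
  check_number(dt_s, "dt_s", lower = 1e-6, upper = 0.05)
  check_number(control_period_s, "control_period_s", lower = dt_s,
               upper = 0.05)
  check_number(sample_rate_hz, "sample_rate_hz", lower = 1)
  check_number(n_breaths, "n_breaths", lower = 0)
  structure(
    list(
      dt_s = dt_s, control_period_s = control_period_s,
      sample_rate_hz = sample_rate_hz, n_breaths = as.integer(n_breaths),
      sensor_noise = sensor_noise, seed = seed,
      peep_margin_cmh2o = peep_margin_cmh2o, margin_mbar = margin_mbar,
      lambda = lambda, c_est0 = c_est0, rk_est0 = rk_est0,
      est_parabolic = isTRUE(est_parabolic), precharge = isTRUE(precharge)
    ),
    class = "vent_sim_config"
  )
}

engine_pars <- function(circuit, lung, settings, sim,
                        rec_start = numeric(0), rec_end = numeric(0),
                        init = NULL) {
  assy <- as_lung_assembly(lung)
  comps <- assy$compartments
  kv <- vapply(circuit$valves, function(v) v$kv, numeric(1))
  noise_on <- !is.null(sim$sensor_noise)
  pars <- list(
    a_a = a_from_kv(kv[["A"]], circuit$a_slope),
    a_b = a_from_kv(kv[["B"]], circuit$a_slope),
    a_c = a_from_kv(kv[["C"]], circuit$a_slope),
    a_d = a_from_kv(kv[["D"]], circuit$a_slope),
    a_s = a_from_kv(circuit$kv_s, circuit$a_slope),
    n_i = circuit$n_inhale, n_e = circuit$n_exhale,
    p_air_abs = circuit$supply_air$pressure_abs_pa,
    p_ox_abs = circuit$supply_o2$pressure_abs_pa,
    f_air = circuit$supply_air$o2_fraction,
    f_ox = circuit$supply_o2$o2_fraction,
    v_res_l = circuit$reservoir_volume_l,
    p_res0_abs = P_ATM_PA,
    f_res0 = 0.21,
    relief_res_abs = P_ATM_PA + bar_to_pa(circuit$relief_reservoir_bar_gauge),
    relief_pat_cm = circuit$relief_patient_cmh2o,
    r_lin = vapply(comps, `[[`, numeric(1), "r_linear"),
    k_par = vapply(comps, `[[`, numeric(1), "k_parabolic"),
    c_ml = vapply(comps, `[[`, numeric(1), "c_lung"),
    v0_ml = vapply(comps, `[[`, numeric(1), "v0_ml"),
    stiff = vapply(comps, `[[`, numeric(1), "stiffening_factor"),
    v_init_ml = vapply(comps, function(cp) {
      cp$volume_ml + cp$c_lung * settings$peep_cmh2o
    }, numeric(1)),
    vt_ml = settings$vt_ml, rr = settings$rr_bpm,
    peep_cm = settings$peep_cmh2o, t_in = settings$t_in_s,
    alarm_pip_cm = settings$alarm_pip_cmh2o, fio2 = settings$fio2,
    control_period_s = sim$control_period_s,
    peep_margin_cm = sim$peep_margin_cmh2o,
    lambda = sim$lambda, margin_pa = sim$margin_mbar * MBAR_PA,
    est_parabolic = as.integer(sim$est_parabolic),
    c_est0 = sim$c_est0, rk_est0 = sim$rk_est0,
    dt = sim$dt_s, n_breaths = sim$n_breaths,
    sample_dt = 1 / sim$sample_rate_hz,
    noise_on = as.integer(noise_on),
    noise_p_cmh2o = if (noise_on) sim$sensor_noise$pressure_cmh2o %||% 0 else 0,
    noise_o2 = if (noise_on) sim$sensor_noise$o2 %||% 0 else 0,
    rec_start = rec_start, rec_end = rec_end,
    precharge = as.integer(sim$precharge),
    corr0 = 0
  )
  if (!is.null(init)) {
    # warm start from a previous run's final state (setting changes mid-
    # ventilation: compliance steps, FiO2 set-point changes, ...)
    if (!is.null(init$p_res_abs)) pars$p_res0_abs <- init$p_res_abs
    if (!is.null(init$f_res)) pars$f_res0 <- init$f_res
    if (!is.null(init$corr_pa)) pars$corr0 <- init$corr_pa
    if (!is.null(init$c_est)) pars$c_est0 <- init$c_est
    if (!is.null(init$rk_est)) pars$rk_est0 <- init$rk_est
    if (!is.null(init$v_ml)) pars$v_init_ml <- rep_len(init$v_ml,
                                                       length(comps))
    pars$precharge <- 0L
  }
  pars
}

#' Final engine state of a trace
#'
#' The reservoir pressure/composition, lung volumes and controller estimates
#' at the end of a run, in the form accepted by the `init` argument of
#' [simulate_ventilation()] — used to chain runs with a setting change in
#' between (a compliance step, a new FiO2 target, ...).
#'
#' @param trace a `vent_trace`.
#' @return a named list.
#' @export
final_state <- function(trace) {
  attr(trace, "final_state")
}

#' Run a ventilation simulation
#'
#' Couples the pneumatic circuit, the lung assembly and the PRVC controller
#' in a fixed-step integration: each step the controller is ticked (at its
#' period), the instantaneous flows are resolved algebraically over the
#' circuit (valve C power law, connector pathway, airway resistances,
#' exhalation pathway), and the reservoir and lung volumes are updated. The
#' only dynamic states are the reservoir pressure/composition and the lung
#' volumes, so the quasi-static resolution is exact up to the step size.
#' Deterministic for a fixed seed.
#'
#' @param circuit a [ventilator_circuit()].
#' @param lung a `vent_lung`, `vent_lung_assembly`, or `"R20/C20"` shorthand.
#' @param settings a [vent_settings()].
#' @param sim a [sim_config()].
#' @param init optional warm-start state from [final_state()] of a previous
#'   run (chains runs across a setting change).
#' @return a tibble of class `vent_trace`, one row per sample, with columns
#'   `time`, `breath`, `phase`, pressures in cmH2O gauge (`p_res`, `p_sys`,
#'   `p_conn`, `p_lung`), flows in l/min (`q_i`, `q_e`), `o2_delivered`,
#'   `v_lung_ml` and the four valve states. Attributes: `breath_log` (one
#'   row per breath: phase timestamps, delivered volume, reservoir target,
#'   estimates, flags), `settings`, `circuit`, `sim`, `relief_events`.
#' @examples
#' \donttest{
#' tr <- simulate_ventilation(ventilator_circuit(), "R20/C20",
#'                            vent_settings(400, 15, 5, "1:3", 0.3),
#'                            sim_config(n_breaths = 8))
#' breath_metrics(tr)
#' }
#' @export
simulate_ventilation <- function(circuit = ventilator_circuit(),
                                 lung = "R20/C20",
                                 settings = vent_settings(400, 15, 5, "1:3",
                                                          0.3),
                                 sim = sim_config(), init = NULL) {
  stopifnot(inherits(circuit, "vent_circuit"),
            inherits(settings, "vent_settings"),
            inherits(sim, "vent_sim_config"))
  if (!is.null(sim$seed)) set.seed(sim$seed)
  out <- run_engine_cpp(engine_pars(circuit, lung, settings, sim,
                                    init = init))
  trace <- tibble::as_tibble(lapply(out$trace, unlist))
  if (sim$n_breaths == 0L) {
    trace <- trace[0, , drop = FALSE]
  }
  for (v in c("valve_a", "valve_b", "valve_c", "valve_d")) {
    trace[[v]] <- as.logical(trace[[v]])
  }
  blog <- tibble::as_tibble(lapply(out$breaths, unlist))
  if (nrow(blog)) blog <- tibble::add_column(blog, breath = seq_len(nrow(blog)),
                                             .before = 1)
  structure(
    trace,
    breath_log = blog,
    settings = settings,
    circuit = circuit,
    sim = sim,
    lung = as_lung_assembly(lung),
    relief_events = out$relief_events,
    patient_relief_events = out$patient_relief_events,
    gas_accounting = lapply(out$gas_accounting, identity),
    final_state = list(
      p_res_abs = out$p_res_final, f_res = out$f_res_final,
      corr_pa = out$corr_final, c_est = out$c_est_final,
      rk_est = out$rk_est_final, v_ml = unlist(out$v_final_ml)
    ),
    class = c("vent_trace", class(trace))
  )
}

#' Gas accounting of a run
#'
#' Atmospheric-equivalent litres supplied through each inlet valve,
#' delivered through Valve C, exhaled through Valve D, and vented by the
#' reservoir relief valve — the terms of the ideal-gas mole balance.
#'
#' @param trace a `vent_trace`.
#' @return a named list of volumes (litres at 1 atm).
#' @export
gas_accounting <- function(trace) {
  attr(trace, "gas_accounting")
}

#' Breath log of a simulation
#'
#' @param trace a `vent_trace`.
#' @return the per-breath controller log tibble.
#' @export
breath_log <- function(trace) {
  attr(trace, "breath_log")
}

#' Long-duration run with periodic snapshots
#'
#' Streams a long simulation, retaining the sampled trace only inside
#' periodic snapshot windows (e.g. 30 s every 10 min) so memory stays
#' bounded, and returns per-window averaged breath metrics together with the
#' drift statistics of tidal volume and PEEP against time (squared
#' correlation of a linear fit).
#'
#' @param circuit,lung,settings,sim as in [simulate_ventilation()].
#' @param total_hours run length in hours.
#' @param snapshot_every_s window cadence, default 600 s.
#' @param snapshot_len_s window length, default 30 s.
#' @param discard_first_breaths breaths excluded from the first window (the
#'   PRVC start-up transient), default 6.
#' @return a list with `snapshots` (tibble: one row per window with mean
#'   metrics), `drift` (tibble with slope and r-squared for `v_t_delivered`
#'   and `peep_achieved` vs time) and `n_breaths_total`.
#' @export
run_long <- function(circuit, lung, settings, sim = sim_config(),
                     total_hours = 2, snapshot_every_s = 600,
                     snapshot_len_s = 30, discard_first_breaths = 6) {
  check_number(total_hours, "total_hours", lower = 1e-4)
  total_s <- total_hours * 3600
  period <- 60 / settings$rr_bpm
  sim$n_breaths <- as.integer(ceiling(total_s / period))
  starts <- seq(0, total_s - snapshot_len_s, by = snapshot_every_s)
  if (!is.null(sim$seed)) set.seed(sim$seed)
  out <- run_engine_cpp(engine_pars(circuit, lung, settings, sim,
                                    rec_start = starts,
                                    rec_end = starts + snapshot_len_s))
  trace <- tibble::as_tibble(lapply(out$trace, unlist))
  for (v in c("valve_a", "valve_b", "valve_c", "valve_d")) {
    trace[[v]] <- as.logical(trace[[v]])
  }
  snaps <- purrr::map_dfr(seq_along(starts), function(i) {
    t_lo <- max(starts[i], if (i == 1L) discard_first_breaths * period else 0)
    w <- trace[trace$time >= t_lo & trace$time < starts[i] +
                 snapshot_len_s, , drop = FALSE]
    m <- suppressWarnings(breath_metrics(w)) # a window may hold no breath
    if (!nrow(m)) return(NULL)
    tibble::tibble(
      snapshot = i, t_mid_s = starts[i] + snapshot_len_s / 2,
      n_breaths = nrow(m),
      v_t_delivered = mean(m$v_t_delivered),
      peep_achieved = mean(m$peep_achieved),
      rr_measured = mean(m$rr_measured),
      fio2_measured = mean(m$fio2_measured)
    )
  })
  drift <- purrr::map_dfr(c("v_t_delivered", "peep_achieved"), function(v) {
    tibble::tibble(metric = v,
                   slope_per_hour = drift_stat(snaps$t_mid_s, snaps[[v]])$slope * 3600,
                   r_squared = drift_stat(snaps$t_mid_s, snaps[[v]])$r2)
  })
  list(snapshots = snaps, drift = drift, n_breaths_total = sim$n_breaths)
}

drift_stat <- function(t, y) {
  if (length(y) < 3 || var(y) < 1e-12) {
    return(list(slope = 0, r2 = 0))
  }
  fit <- lm(y ~ t)
  slope <- unname(coef(fit)[2])
  # a fitted change below 0.1% of the mean over the whole run is beneath
  # measurement resolution: report it as driftless rather than letting a
  # sub-resolution monotone wiggle inflate the correlation
  change <- abs(slope) * diff(range(t))
  if (change < 1e-3 * (abs(mean(y)) + 1e-9)) {
    return(list(slope = slope, r2 = 0))
  }
  list(slope = slope, r2 = suppressWarnings(summary(fit))$r.squared)
}
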