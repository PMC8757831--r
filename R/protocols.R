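# Experiment protocols: the 243-case parametric sweep, the ISO 80601-2-12
# test suite (with its blank-cell inheritance convention and the parallel
# two-lung cases), valve flow-coefficient design-space sweeps, and the
# long-duration durability run.

#' ISO 80601-2-12 tolerance bands
#'
#' Volume within -(4 ml + 15%) to +(4 ml + 15%) of target, PEEP within
#' +/- 2 cmH2O, FiO2 within +/- 5% of the target concentration.
#'
#' @param vt_target_ml,peep_target,fio2_target targets.
#' @return a named list of band edges.
#' @export
iso_bands <- function(vt_target_ml, peep_target, fio2_target) {
  list(
    vt_lo = 0.85 * vt_target_ml - 4, vt_hi = 1.15 * vt_target_ml + 4,
    peep_lo = peep_target - 2, peep_hi = peep_target + 2,
    fio2_lo = fio2_target * 0.95, fio2_hi = fio2_target * 1.05
  )
}

#' Full factorial of the parametric sweep
#'
#' Tidal volume {200, 400, 600} ml x respiratory rate {10, 20, 35} bpm x
#' PEEP {5, 10, 15} cmH2O x I:E {1:1, 1:2, 1:4} x FiO2 {60, 75, 90}% =
#' 243 cases, in Cartesian-product order. Screen with
#' [screen_sweep_cases()] (expected peak pressure <= 45 cmH2O against the
#' R20/C20 reference lung) before running.
#'
#' @return a 243-row tibble with columns `vt_ml`, `rr_bpm`, `peep_cmh2o`,
#'   `ie`, `e_ratio`, `fio2_pct`.
#' @export
parametric_sweep_cases <- function() {
  grid <- tidyr::expand_grid(
    vt_ml = c(200, 400, 600),
    rr_bpm = c(10, 20, 35),
    peep_cmh2o = c(5, 10, 15),
    e_ratio = c(1, 2, 4),
    fio2_pct = c(60, 75, 90)
  )
  grid$ie <- sprintf("1:%g", grid$e_ratio)
  grid[, c("vt_ml", "rr_bpm", "peep_cmh2o", "ie", "e_ratio", "fio2_pct")]
}

#' The ISO 80601-2-12:2020 test suite
#'
#' The Default condition plus Tests 1-7. Blank table cells inherit the value
#' from the previous row; the Default row's dashes (lung and FiO2
#' unspecified) are resolved to the reference lung and the FiO2 of the
#' subsequent test. Tests 1 and 2 approximate a 50 ml/cmH2O compliance with
#' two test lungs in parallel (EasyLung R20/C25 plus SmartLung R5/C30 or
#' R20/C30); because their resistances differ the compliances are not
#' directly additive.
#'
#' @param default_lung lung shorthand for the Default row, default
#'   `"R20/C20"`.
#' @param default_fio2_pct FiO2 for the Default row, default 30.
#' @return an 8-row tibble with inheritance resolved (no blank fields):
#'   `id`, `c`, `r`, `vt_ml`, `rr_bpm`, `t_in_s`, `fio2_pct`, `peep_cmh2o`,
#'   `ie`, `parallel`, `lung_label`.
#' @export
iso_suite <- function(default_lung = "R20/C20", default_fio2_pct = 30) {
  ref <- parse_lung(default_lung)
  raw <- tibble::tribble(
    ~id,       ~c, ~r, ~vt_ml, ~rr_bpm, ~t_in_s, ~fio2_pct, ~peep_cmh2o, ~ie,
    "Default", ref$c_lung, ref$r_rated, 400, 15, 1, default_fio2_pct, 5, "1:3",
    "1",       50, 5,  500, 20, 1, 30, 5,  "1:2",
    "2",       NA, 20, NA,  12, 1, 90, 10, "1:4",
    "3",       20, 5,  NA,  20, 1, NA, 5,  "1:2",
    "4",       NA, 20, NA,  NA, 1, 30, 10, NA,
    "5",       NA, NA, 300, NA, 1, NA, 5,  NA,
    "6",       NA, 50, NA,  12, 1, 90, 10, "1:4",
    "7",       10, NA, NA,  20, 1, 30, 10, "1:2"
  )
  out <- tidyr::fill(raw, dplyr::everything(), .direction = "down")
  out$parallel <- out$id %in% c("1", "2")
  out$lung_label <- ifelse(
    out$parallel,
    paste0("R20/C25 + R", out$r, "/C30"),
    sprintf("R%g/C%g", out$r, out$c)
  )
  out$lung_label[out$id == "Default"] <- ref$label
  out
}

#' Lung assembly for an ISO case
#'
#' @param case one row of [iso_suite()].
#' @param ... passed to [lung_compartment()] (e.g. `resistance_model`).
#' @return a `vent_lung_assembly`.
#' @export
iso_lung <- function(case, ...) {
  if (isTRUE(case$parallel)) {
    lung_assembly(
      lung_compartment(20, 25, label = "EasyLung R20/C25", ...),
      lung_compartment(case$r, 30,
                       label = sprintf("SmartLung R%g/C30", case$r), ...)
    )
  } else {
    lung_assembly(lung_compartment(case$r, case$c,
                                   label = sprintf("R%g/C%g", case$r, case$c),
                                   ...))
  }
}

#' Settings for an ISO case
#'
#' @param case one row of [iso_suite()].
#' @return a [vent_settings()].
#' @export
iso_settings <- function(case) {
  vent_settings(case$vt_ml, case$rr_bpm, case$peep_cmh2o, case$ie,
                case$fio2_pct / 100)
}

#' Run the ISO 80601-2-12 suite
#'
#' Simulates every case of [iso_suite()] and summarises the steady-state
#' breaths (the analysis window discards the transition breaths) against the
#' ISO tolerance bands.
#'
#' @param circuit a [ventilator_circuit()] (its supplies select the 4-bar or
#'   oxygen-concentrator configuration).
#' @param suite the case table, default [iso_suite()].
#' @param sim a [sim_config()]; its `n_breaths` sets the run length.
#' @param window breaths analysed, default `6:(n_breaths - 1)`.
#' @param keep_metrics keep the per-breath metric tables in a list column.
#' @return a tibble with one row per case: mean metrics over the window and
#'   logical `pass_vt`, `pass_peep`, `pass_fio2`, `pass`.
#' @export
run_iso_suite <- function(circuit = ventilator_circuit(),
                          suite = iso_suite(),
                          sim = sim_config(n_breaths = 40),
                          window = NULL, keep_metrics = FALSE) {
  window <- window %||% seq(6L, max(6L, sim$n_breaths - 1L))
  purrr::map_dfr(seq_len(nrow(suite)), function(i) {
    case <- suite[i, ]
    run_case_summary(circuit, iso_lung(case), iso_settings(case), sim,
                     window, id = case$id, keep_metrics = keep_metrics)
  })
}

run_case_summary <- function(circuit, lung, settings, sim, window, id = NA,
                             keep_metrics = FALSE) {
  tr <- simulate_ventilation(circuit, lung, settings, sim)
  m <- breath_metrics(tr)
  m <- m[m$breath %in% window, , drop = FALSE]
  b <- iso_bands(settings$vt_ml, settings$peep_cmh2o, settings$fio2)
  out <- tibble::tibble(
    id = as.character(id),
    vt_target = settings$vt_ml, peep_target = settings$peep_cmh2o,
    fio2_target = settings$fio2,
    n_breaths = nrow(m),
    v_t_delivered = mean(m$v_t_delivered),
    peep_achieved = mean(m$peep_achieved),
    rr_measured = mean(m$rr_measured),
    fio2_measured = mean(m$fio2_measured),
    pip = mean(m$pip), p_plat = mean(m$p_plat),
    tex_star = mean(m$tex_star, na.rm = TRUE),
    stacking = any(m$stacking),
    alarms = sum(breath_log(tr)$alarm)
  )
  out$pass_vt <- out$v_t_delivered >= b$vt_lo & out$v_t_delivered <= b$vt_hi
  out$pass_peep <- abs(out$peep_achieved - settings$peep_cmh2o) <= 2
  out$pass_fio2 <- out$fio2_measured >= b$fio2_lo &
    out$fio2_measured <= b$fio2_hi
  out$pass <- out$pass_vt & out$pass_peep & out$pass_fio2
  if (keep_metrics) out$metrics <- list(m)
  out
}

#' Replace both supply pressures of a circuit
#'
#' Convenience for the oxygen-concentrator configuration (both supplies at
#' 1.3 bar gauge) versus hospital lines (4 bar).
#'
#' @param circuit a [ventilator_circuit()].
#' @param bar_gauge new supply pressure for air and oxygen.
#' @return the modified circuit.
#' @export
with_supplies <- function(circuit, bar_gauge) {
  circuit$supply_air <- gas_supply(bar_gauge,
                                   circuit$supply_air$o2_fraction, "air")
  circuit$supply_o2 <- gas_supply(bar_gauge,
                                  circuit$supply_o2$o2_fraction, "oxygen")
  circuit
}

#' Replace one valve flow coefficient
#'
#' @param circuit a [ventilator_circuit()].
#' @param valve `"ab"` (both inlet valves), `"c"` or `"d"`.
#' @param kv new flow coefficient.
#' @return the modified circuit.
#' @export
with_kv <- function(circuit, valve = c("ab", "c", "d"), kv) {
  valve <- match.arg(valve)
  if (valve == "ab") {
    circuit$valves$A <- valve_spec(kv, "A")
    circuit$valves$B <- valve_spec(kv, "B")
  } else if (valve == "c") {
    circuit$valves$C <- valve_spec(kv, "C")
  } else {
    circuit$valves$D <- valve_spec(kv, "D")
  }
  circuit
}

#' Valve flow-coefficient design-space sweep
#'
#' Re-runs the ISO suite at each grid value of the chosen valve's flow
#' coefficient, the other valves held at the prototype defaults, and records
#' steady-state metrics and pass/fail per case. Pass criteria: tidal volume
#' within +/-(4 ml + 15%) for the inlet (A/B) and inhalation (C) valves;
#' achieved PEEP within +/- 2 cmH2O for the exhalation valve (D). PiP,
#' PiP - p_plat and Tex* are recorded alongside.
#'
#' @param valve `"ab"`, `"c"` or `"d"`.
#' @param grid strictly increasing Kv grid (m3/h/bar^0.5).
#' @param circuit base circuit (prototype defaults).
#' @param suite ISO case table.
#' @param sim simulation config; default 20 breaths at dt = 0.5 ms.
#' @param window analysis breaths, default `6:(n_breaths - 1)`.
#' @param fail_fast skip the remaining cases of a grid point after its first
#'   failure (the point is already failed); per-point pass/fail and the
#'   thresholds are unaffected. Default TRUE.
#' @param alarm_pip_cmh2o peak-pressure alarm during the sweep. Default
#'   `Inf`: the design-space exploration characterises the plant across the
#'   whole grid (oversized inhalation valves transiently spike the connector
#'   pressure, which the prototype's safety alarm would abort); set 45 to
#'   sweep with the safety system armed.
#' @return a tibble of class `vent_kv_sweep`: one row per (kv, case) pair
#'   actually simulated, with metrics and a `pass` flag; attribute `valve`.
#' @seealso [kv_threshold()]
#' @export
kv_sweep <- function(valve = c("ab", "c", "d"), grid,
                     circuit = ventilator_circuit(), suite = iso_suite(),
                     sim = sim_config(n_breaths = 20), window = NULL,
                     fail_fast = TRUE, alarm_pip_cmh2o = Inf) {
  valve <- match.arg(valve)
  if (is.unsorted(grid, strictly = TRUE)) {
    stopf("`grid` must be strictly increasing")
  }
  window <- window %||% seq(6L, max(6L, sim$n_breaths - 1L))
  lungs <- lapply(seq_len(nrow(suite)), function(i) iso_lung(suite[i, ]))
  setts <- lapply(seq_len(nrow(suite)), function(i) {
    s <- iso_settings(suite[i, ])
    s$alarm_pip_cmh2o <- alarm_pip_cmh2o
    s
  })
  rows <- list()
  for (kv in grid) {
    circ <- with_kv(circuit, valve, kv)
    for (i in seq_len(nrow(suite))) {
      s <- run_case_summary(circ, lungs[[i]], setts[[i]], sim, window,
                            id = suite$id[i])
      s$kv <- kv
      s$pass <- if (valve == "d") s$pass_peep else s$pass_vt
      rows[[length(rows) + 1L]] <- s
      if (fail_fast && !s$pass) break
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[, c("kv", setdiff(names(out), "kv"))]
  structure(out, valve = valve,
            class = c("vent_kv_sweep", class(out)))
}

#' Usable-range boundary of a Kv sweep
#'
#' @param sweep a [kv_sweep()] result.
#' @param mode `"smallest_pass_all"`: the smallest grid value at which every
#'   case passes; `"largest_fail_any"`: the largest grid value at which at
#'   least one case fails.
#' @return the Kv boundary (NA when no grid point qualifies).
#' @export
kv_threshold <- function(sweep, mode = c("smallest_pass_all",
                                         "largest_fail_any")) {
  mode <- match.arg(mode)
  per_point <- dplyr::summarise(dplyr::group_by(sweep, .data$kv),
                                all_pass = all(.data$pass), .groups = "drop")
  if (mode == "smallest_pass_all") {
    ok <- per_point$kv[per_point$all_pass]
    if (!length(ok)) NA_real_ else min(ok)
  } else {
    bad <- per_point$kv[!per_point$all_pass]
    if (!length(bad)) NA_real_ else max(bad)
  }
}

#' Run the parametric ventilation sweep
#'
#' Simulates (a subset of) the screened factorial cases against a single
#' test lung and summarises the last breaths of each short run, mirroring
#' the 15-breath-per-case schedule with the first 6 transition breaths
#' discarded.
#'
#' @param cases rows of [parametric_sweep_cases()] (screen first).
#' @param circuit a [ventilator_circuit()].
#' @param lung the test lung, default `"R20/C20"`.
#' @param sim simulation config; default 15 breaths.
#' @param window analysis breaths, default 7:15 (the last 9).
#' @return tibble of per-case mean metrics.
#' @export
run_parametric_sweep <- function(cases, circuit = ventilator_circuit(),
                                 lung = "R20/C20",
                                 sim = sim_config(n_breaths = 15),
                                 window = 7:15) {
  assy <- as_lung_assembly(lung)
  purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    cs <- cases[i, ]
    settings <- vent_settings(cs$vt_ml, cs$rr_bpm, cs$peep_cmh2o, cs$ie,
                              cs$fio2_pct / 100)
    run_case_summary(circuit, assy, settings, sim, window, id = i)
  })
}

#' Durability run specification
#'
#' The long-run configuration: R20/C25 test lung, FiO2 21%, tidal volume
#' 400 ml, PEEP 5 cmH2O, RR 30 bpm, I:E 1:2, with 30 s of data acquired
#' every 10 min.
#'
#' @return a list with `settings`, `lung`, `snapshot_every_s`,
#'   `snapshot_len_s`.
#' @export
durability_protocol <- function() {
  list(
    settings = vent_settings(400, 30, 5, "1:2", 0.21),
    lung = "R20/C25",
    snapshot_every_s = 600,
    snapshot_len_s = 30
  )
}

#' Run the durability protocol
#'
#' @param circuit a [ventilator_circuit()].
#' @param total_hours simulated duration (desk-scale default 2 h).
#' @param sim a [sim_config()].
#' @param discard_first_breaths cold-start breaths excluded from the drift
#'   analysis (the PRVC adaptation settles from an unknown lung within about
#'   25 breaths); default 30.
#' @return see [run_long()].
#' @export
run_durability <- function(circuit = ventilator_circuit(), total_hours = 2,
                           sim = sim_config(), discard_first_breaths = 30) {
  p <- durability_protocol()
  run_long(circuit, p$lung, p$settings, sim, total_hours = total_hours,
           snapshot_every_s = p$snapshot_every_s,
           snapshot_len_s = p$snapshot_len_s,
           discard_first_breaths = discard_first_breaths)
}
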