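# Run configuration files (YAML/JSON) and result output (CSV + JSON).
# All quantities in file interfaces are clinical units with the unit in the
# key name; conversion to engine units happens once at load.

CONFIG_SCHEMA_VERSION <- 1L

config_defaults <- function() {
  list(
    circuit = list(
      kv_a = 0.12, kv_b = 0.12, kv_c = 0.17, kv_d = 0.70, kv_s = 1.0,
      n_inhale = 0.5, n_exhale = 0.5,
      supply_air_bar_gauge = 4, supply_o2_bar_gauge = 4,
      o2_supply_fraction = 1.0,
      reservoir_volume_l = 2,
      relief_reservoir_bar_gauge = 1.0, relief_patient_cmh2o = 60
    ),
    lung = list(label = "R20/C20", v0_ml = 1000,
                resistance_model = "parabolic", stiffening_factor = 50),
    settings = list(vt_ml = 400, rr_bpm = 15, peep_cmh2o = 5, ie = "1:3",
                    fio2_pct = 30, alarm_pip_cmh2o = 45),
    sim = list(dt_ms = 0.5, control_period_ms = 5, sample_rate_hz = 200,
               n_breaths = 20, seed = NULL,
               sensor_noise_pressure_cmh2o = 0, sensor_noise_o2 = 0)
  )
}

check_keys <- function(given, allowed, where) {
  bad <- setdiff(names(given), allowed)
  if (length(bad)) {
    stopf("unknown key(s) in `%s`: %s", where, paste(bad, collapse = ", "))
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON run configuration with sections `circuit`, `lung`,
#' `settings` and `sim`, rejects unknown keys, fills defaults, constructs the
#' corresponding package objects and echoes the derived timing quantities
#' (T_in, T_ex, mean inspiratory flow). A minimal (even empty) config runs
#' the Default ISO case.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a list of class `vent_run_config` with elements `circuit`, `lung`,
#'   `settings`, `sim`, `echo` (the fully resolved configuration including
#'   derived values) and `schema_version`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stopf("config must be .yaml, .yml or .json: %s", path)
  }
  raw <- raw %||% list()
  check_keys(raw, c("schema_version", "circuit", "lung", "settings", "sim"),
             "config")
  if (!is.null(raw$schema_version) &&
      raw$schema_version != CONFIG_SCHEMA_VERSION) {
    stopf("unsupported schema_version %s (this package reads version %d)",
          raw$schema_version, CONFIG_SCHEMA_VERSION)
  }
  def <- config_defaults()
  for (sec in names(def)) {
    check_keys(raw[[sec]] %||% list(), names(def[[sec]]), sec)
  }
  cfg <- lapply(names(def), function(sec) {
    modifyList(def[[sec]], as.list(raw[[sec]] %||% list()))
  })
  names(cfg) <- names(def)

  ci <- cfg$circuit
  circuit <- ventilator_circuit(
    kv_a = ci$kv_a, kv_b = ci$kv_b, kv_c = ci$kv_c, kv_d = ci$kv_d,
    kv_s = ci$kv_s, n_inhale = ci$n_inhale, n_exhale = ci$n_exhale,
    supply_air = gas_supply(ci$supply_air_bar_gauge, 0.21, "air"),
    supply_o2 = gas_supply(ci$supply_o2_bar_gauge, ci$o2_supply_fraction,
                           "oxygen"),
    reservoir_volume_l = ci$reservoir_volume_l,
    relief_reservoir_bar_gauge = ci$relief_reservoir_bar_gauge,
    relief_patient_cmh2o = ci$relief_patient_cmh2o
  )
  lu <- cfg$lung
  lung <- parse_lung(lu$label, v0_ml = lu$v0_ml,
                     resistance_model = lu$resistance_model,
                     stiffening_factor = lu$stiffening_factor)
  st <- cfg$settings
  settings <- vent_settings(st$vt_ml, st$rr_bpm, st$peep_cmh2o, st$ie,
                            st$fio2_pct / 100, st$alarm_pip_cmh2o)
  si <- cfg$sim
  noise <- NULL
  if ((si$sensor_noise_pressure_cmh2o %||% 0) > 0 ||
      (si$sensor_noise_o2 %||% 0) > 0) {
    noise <- list(pressure_cmh2o = si$sensor_noise_pressure_cmh2o,
                  o2 = si$sensor_noise_o2)
  }
  sim <- sim_config(dt_s = si$dt_ms / 1000,
                    control_period_s = si$control_period_ms / 1000,
                    sample_rate_hz = si$sample_rate_hz,
                    n_breaths = si$n_breaths,
                    sensor_noise = noise, seed = si$seed)
  echo <- cfg
  echo$derived <- list(t_in_s = settings$t_in_s, t_ex_s = settings$t_ex_s,
                       q_bar_ls = settings$q_bar_ls)
  structure(
    list(circuit = circuit, lung = lung, settings = settings, sim = sim,
         echo = echo, schema_version = CONFIG_SCHEMA_VERSION),
    class = "vent_run_config"
  )
}

#' Write simulation outputs
#'
#' Writes `trace.csv` (one row per sample, engine schema), `breaths.csv`
#' (per-breath metrics) and `summary.json` (schema version, settings echo,
#' mean metrics, ISO pass/fail bands, alarm and relief counts). Content is
#' deterministic for a fixed seed.
#'
#' @param trace a `vent_trace`.
#' @param metrics per-breath metrics, default `breath_metrics(trace)`.
#' @param outdir output directory (created if needed).
#' @param window breaths summarised in the JSON, default all complete ones.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(trace, metrics = NULL, outdir, window = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  metrics <- metrics %||% breath_metrics(trace)
  paths <- c(trace = file.path(outdir, "trace.csv"),
             breaths = file.path(outdir, "breaths.csv"),
             summary = file.path(outdir, "summary.json"))
  utils::write.csv(as.data.frame(trace), paths["trace"], row.names = FALSE)
  utils::write.csv(as.data.frame(metrics), paths["breaths"],
                   row.names = FALSE)
  settings <- attr(trace, "settings")
  m <- if (!is.null(window)) metrics[metrics$breath %in% window, ] else
    metrics
  summary <- list(schema_version = CONFIG_SCHEMA_VERSION)
  if (!is.null(settings)) {
    b <- iso_bands(settings$vt_ml, settings$peep_cmh2o, settings$fio2)
    summary$settings <- list(
      vt_ml = settings$vt_ml, rr_bpm = settings$rr_bpm,
      peep_cmh2o = settings$peep_cmh2o, e_ratio = settings$e_ratio,
      fio2 = settings$fio2, t_in_s = settings$t_in_s,
      t_ex_s = settings$t_ex_s
    )
    summary$bands <- b
    if (nrow(m)) {
      summary$results <- list(
        n_breaths = nrow(m),
        v_t_delivered = mean(m$v_t_delivered),
        peep_achieved = mean(m$peep_achieved),
        fio2_measured = mean(m$fio2_measured),
        pass_vt = mean(m$v_t_delivered) >= b$vt_lo &&
          mean(m$v_t_delivered) <= b$vt_hi,
        pass_peep = abs(mean(m$peep_achieved) - settings$peep_cmh2o) <= 2,
        pass_fio2 = mean(m$fio2_measured) >= b$fio2_lo &&
          mean(m$fio2_measured) <= b$fio2_hi
      )
    }
    blog <- breath_log(trace)
    summary$alarms <- if (!is.null(blog) && nrow(blog)) sum(blog$alarm) else 0
    summary$relief_events <- attr(trace, "relief_events") %||% 0
  }
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a trace CSV back into the engine schema
#'
#' External recordings can be mapped onto the engine schema by a named
#' `columns` vector (`c(q_i = "Flow", p_sys = "Paw", ...)`).
#'
#' @param path CSV file.
#' @param columns optional named character vector mapping engine schema
#'   column names to file column names.
#' @return a tibble in the engine trace schema.
#' @export
read_trace <- function(path, columns = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (!is.null(columns)) {
    for (nm in names(columns)) {
      df[[nm]] <- df[[columns[[nm]]]]
    }
  }
  for (v in intersect(c("valve_a", "valve_b", "valve_c", "valve_d"),
                      names(df))) {
    df[[v]] <- as.logical(df[[v]])
  }
  df
}
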