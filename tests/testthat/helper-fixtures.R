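# Shared fixtures: everything is generated in code at test time.

quick_sim <- function(n_breaths = 10, ...) {
  sim_config(n_breaths = n_breaths, ...)
}

default_settings <- function(...) {
  vent_settings(400, 15, 5, "1:3", 0.3, ...)
}

# R-level fixed-step free-exhalation stepper built from the lung-module
# operations: a single compartment discharging through its own (linear)
# resistance against a constant back pressure.
step_exhalation <- function(comp, peep_cmh2o, t_end_s, dt_s = 5e-4) {
  n <- ceiling(t_end_s / dt_s)
  t <- numeric(n + 1)
  p <- numeric(n + 1)
  p[1] <- lung_pressure(comp)
  for (i in seq_len(n)) {
    q <- lung_flow(comp, peep_cmh2o) # signed, negative out of the lung
    comp <- update_volume(comp, q, dt_s)
    t[i + 1] <- i * dt_s
    p[i + 1] <- lung_pressure(comp)
  }
  data.frame(time = t, p_lung = p)
}
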