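# onoffvent

Desk-scale, deterministic simulation of a mechanical ventilator built
entirely from **on-off (2/2) solenoid valves** — no proportional valves, no
flow sensors. Two inlet valves (oxygen and air) charge a 2-litre mixing
reservoir; an inhalation valve releases the pressurised mixture to the
patient; an exhalation valve vents the lung to atmosphere; two pressure
sensors and an oxygen sensor close the loop. The package is for respiratory
and medical-device engineers who need to answer the supply-chain question
this architecture raises: **over what ranges of valve flow coefficients
(Kv) does the system still meet ISO 80601-2-12 ventilation tolerances?**

## What it implements

* **Pneumatics** — calibrated power-law pathways
  `q [l/min] = a (Δp [mbar])^n` with `a = 13.1 Kv` and `n = 0.5` for
  orifice-dominated paths; isothermal ideal-gas reservoir with mole-balance
  oxygen mixing and mechanical relief ceilings.
* **Test-lung mechanics** — single- and two-compartment R-C lungs with
  orifice-plate (parabolic) or linear resistance and volume-limited
  compliance (`p = V/C` up to the bag volume `V0`, stiffening beyond; a
  C = 20 ml/cmH2O lung with a 1000 ml bag maxes out at 50 cmH2O).
* **PRVC controller** — the six-phase timing scheduler: flow-sensorless
  volume delivery integrated from the two pressure sensors
  (`q_I = a_I (p_res − p_sys)^{n_I}`), breath-to-breath adaptation of the
  reservoir pressure target
  `p_target = PiP_est + P_atm V_T/V_res + margin + Σ λ(V_T − V_delivered)P_atm/V_res`,
  sequential O2→air charging solving the FiO2 mole balance, exhalation
  termination at PEEP via `p_lung = p_sys + R_air q_E`, and a 45 cmH2O
  peak-pressure alarm (safe state: inhalation closed, exhalation open).
* **Engine** — fixed-step (0.5 ms) integration with algebraic flow
  resolution (compiled core), 200 Hz traces, optional seeded sensor noise.
* **Metrics** — per-breath ISO 80601-2-12 quantities: trapezoidal tidal
  volume, last-50-ms PEEP, valve-edge respiratory rate, exhalation-averaged
  FiO2, peak/plateau pressures, the expiratory decay fraction Tex*, plus
  Bland–Altman agreement statistics with `tidy()`/`glance()`/`autoplot()`.
* **Protocols** — the 243-case clinical-settings factorial with
  `PiP = PEEP + V_T/C + R q̄` screening at 45 cmH2O, the 8-case
  ISO 80601-2-12 suite (blank table cells inherited, two-lung parallel
  assemblies for the high-compliance cases), valve Kv design-space sweeps
  on 0.01-step grids, and a long-run durability/drift protocol.

## Worked example

Ventilate a severe-disease test lung (R20/C20) at the Default condition
(V_T 400 ml, RR 15, PEEP 5 cmH2O, I:E 1:3, FiO2 30 %) and extract
steady-state breath metrics:

```r
library(onoffvent)

circuit  <- ventilator_circuit()        # prototype Kv: A/B 0.12, C 0.17, D 0.70
settings <- vent_settings(vt_ml = 400, rr_bpm = 15, peep_cmh2o = 5,
                          ie = "1:3", fio2 = 0.30)
trace <- simulate_ventilation(circuit, "R20/C20", settings,
                              sim_config(n_breaths = 20))
m <- breath_metrics(trace)
m[m$breath %in% 15:19, c("breath", "v_t_delivered", "peep_achieved",
                         "rr_measured", "fio2_measured", "pip", "p_plat",
                         "tex_star")]
#>   breath v_t_delivered peep_achieved rr_measured fio2_measured    pip p_plat tex_star
#> 1     15       396.733         5.892          15         0.302 26.785 25.762    0.282
#> 2     16       396.733         5.892          15         0.301 26.785 25.761    0.282
#> 3     17       396.733         5.892          15         0.302 26.785 25.761    0.282
#> 4     18       396.733         5.892          15         0.300 26.785 25.761    0.282
#> 5     19       396.733         5.891          15         0.301 26.785 25.761    0.282
```

Delivered volume sits within the ISO band (±(4 ml + 15 %) of 400 ml),
achieved PEEP ~0.9 cmH2O above target (the controller is biased never to
undershoot PEEP), FiO2 on target, and exhalation uses only 28 % of the
allotted expiratory time. Agreement between the controller's internal
volumetry and the trace-derived tidal volume:

```r
bl <- breath_log(trace)
glance(bland_altman(bl$delivered_true_ml[m$breath], m$v_t_delivered))
#>   mean_diff sd_diff loa_low loa_high    slope  slope_p r_squared     n
#>      -0.657  0.0220  -0.701   -0.613 -0.00320 6.06e-17     0.985    19
```

a −0.7 ml bias from trapezoidal sampling at 200 Hz. `autoplot(trace)`
draws the pressure/flow/volume waveform panels; `run_iso_suite()`,
`kv_sweep()` and `run_durability()` drive the full experiment protocols,
e.g.

```r
sweep <- kv_sweep("c", seq(0.02, 0.80, 0.01))   # inhalation-valve design space
kv_threshold(sweep, "largest_fail_any")         # usable-range boundary
```

A thin command-line front end with `simulate`/`iso`/`sweep`/`kvsweep`/
`durability` subcommands lives at `inst/cli/onoffvent.R`, and an example
YAML run configuration at `inst/extdata/default_run.yaml`.

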