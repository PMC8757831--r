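---
title: "Modelling a PRVC ventilator built from on-off solenoid valves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a PRVC ventilator built from on-off solenoid valves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onoffvent)
```

## The system being simulated

`onoffvent` is a desk-scale, deterministic simulator of a mechanical
ventilator whose only actuated parts are four on-off (2/2) solenoid valves.
Two inlet valves (A: oxygen, B: air) charge a fixed 2-litre reservoir with
the gas mixture for the next breath; an inhalation valve (C) releases the
pressurised mixture to the patient; an exhalation valve (D) vents the lung
to atmosphere. Two pressure sensors (reservoir and delivery manifold) and an
oxygen sensor close the loop — there is no flow sensor and no proportional
valve. The package exists to answer the design question such a circuit
poses: over what ranges of valve flow coefficients (Kv) does the system
still meet ISO 80601-2-12 ventilation tolerances, so that the design can be
built from whatever valves a local supply chain offers?

## Lumped-parameter pneumatics

Every pneumatic pathway is a calibrated power law

\[ q = a\,\Delta p^{\,n}, \]

with `q` in l/min and `Δp` in mbar, zero flow at zero drop, and `n = 0.5`
for orifice-dominated pathways. The coefficient scales linearly with the
valve flow coefficient, `a = 13.1 Kv`. Two unit readings of that slope are
arithmetically possible (`m³/h` against `bar`, or `l/min` against `mbar`);
the package adopts the latter. The choice is fixed by the physics it must
reproduce: with `q [l/min] = 13.1 Kv (Δp [mbar])^{1/2}` and the 1 bar gauge
reservoir relief ceiling, the recharge-rate arithmetic yields usable inlet
valves down to Kv ≈ 0.02 at 4 bar supplies, the ceiling-limited delivery
rate fails 500 ml tidal volumes below Kv_C ≈ 0.07, and the
reservoir-depletion law (flow decays linearly in time as the reservoir
empties — see below) yields a ≈50–60 % inspiratory flow decay at the
prototype's Kv_C = 0.17. The alternative reading puts the Kv_C boundary
near 0.15 and the flow decay near 18 %, which does not describe this
system.

The reservoir is an isothermal ideal-gas store: charging by an
atmospheric-equivalent volume `dV` raises its pressure by
`P_atm · dV / V_res`, the oxygen fraction updates as a mole-weighted
mixture, and discharging leaves the composition unchanged (well mixed). All
pathway flows are booked as atmospheric-equivalent volumes, which makes
mole conservation exact by construction; the test suite checks the closed
balance to 10⁻⁶ relative. Tubing gas compliance (~0.6 ml/cmH2O, one to two
orders below lung compliance) is omitted. Mechanical relief valves clamp
the reservoir at 1 bar gauge (configurable) and log patient-side excursions
above 60 cmH2O.

A useful closed form falls out of this bookkeeping: while valve C is open
against a slowly varying downstream pressure, `d(Δp)/dt = -(P_atm/V_res) q`
with `q = a√Δp` gives a *linear* decay of flow in time,
`q(t) = q₀ − (P_atm a²/2V_res) t`. The three inhalation regimes are then
transparent: an undersized valve C rides the relief ceiling and delivers a
nearly constant (but insufficient) flow, like volume-controlled
ventilation; a mid-sized valve delivers the set volume exactly within the
inspiratory time with the flow decaying ~50–60 % (pressure-regulated
behaviour); an oversized valve dumps the depletion margin quickly, spiking
the connector pressure early before settling to the same plateau. In all
three the peak *lung* pressure is nearly identical, because it is fixed by
the delivered volume and the compliance, not by the valve.

## Test-lung mechanics

Commercial test lungs are a silicone bag in a leaf-spring casing with an
orifice-plate resistor. The package models a compartment as:

* **parabolic resistance** by default, `Δp = k q²` with
  `k = R_rated / q_ref` anchored at the rating flow (60 l/min unless
  stated), and a purely linear option (`Δp = R q`) selectable per
  compartment — this is the "rated versus flow-corrected" choice, exposed
  as `resistance_model`;
* **volume-limited compliance**: `p = V/C` up to the usable bag volume
  `V0`, beyond which the incremental stiffness is multiplied by a
  stiffening factor (default 50; the bag is far stiffer than the leaf
  spring). The default `V0` is 1000 ml at every rated compliance — the
  bag volume itself — which places the maximum expansion of a
  20 ml/cmH2O lung at 50 cmH2O of recoil pressure. The pro-rata reduction
  of `V0` with compliance that the sliding-bar mechanism can introduce is
  available through the `v0_ml` argument rather than as a default, because
  a pro-rata default would contradict the 50 cmH2O figure and make the
  standard ISO case with PEEP 10 and 500 ml undeliverable.

Two compartments can be teed into the same connector
(`lung_assembly()`); the shared connector pressure drives both through
their own resistances, so the combined quasi-static compliance is *less*
than the sum and gas can shuttle between compartments when the valves are
closed. The ISO suite uses this construction for its two high-compliance
cases.

## The six-phase controller

One breath of period `60/RR` runs through six phases. Phase 1: valve C
opens and the controller integrates the delivered volume from the two
pressure sensors through the inhalation power law (flow-sensorless
volumetry; the trapezoidal tick integral agrees with the true volume gain
to within 2 %). C closes when the set tidal volume has been delivered.
Phase 2: all valves closed until the inspiratory time
`T_in = 60/RR · 1/(1+E)`. Phase 3: at `T_in` exactly, D opens (exhalation)
and A opens (oxygen charge). Phase 4: A hands over to B once the planned
oxygen share of the reservoir pressure rise is charged. Phase 5: B closes
at the reservoir target. Phase 6: D closes when the estimated lung pressure
reaches PEEP. The exhalation and charging tracks run as independent
sub-machines; the reported phase label is derived from their joint state.

Design choices that the published description leaves open, and how they
were resolved:

* **Reservoir-target adaptation.** The target is
  `P_atm + PiP_est + P_atm·V_T/V_res + margin + correction`, where
  `PiP_est = PEEP + V_T/C_est + R_est·q̄` is the ideal-lung peak-pressure
  estimate, the depletion term is the ideal-gas cost of the breath, the
  fixed margin defaults to 20 mbar, and the correction integrates
  `λ (V_T − V_T,delivered) P_atm/V_res` breath to breath with `λ = 0.7`,
  each step clipped to ±20 % of the gauge target, the whole target clamped
  at the relief ceiling. The correction only grows while breaths run
  short, so the steady state sits just above the minimum that completes
  delivery within `T_in` — which is what produces the medium-regime flow
  decay.
* **End-inspiratory hold.** Valve C is hard-closed three control periods
  before `T_in`. The hold guarantees at least two all-closed control ticks
  each breath, which is the minimum the plateau-pressure sample needs; the
  plateau in turn feeds the compliance estimate
  (`C_est = delivered/(p_plat − p_start)`) and the exhalation-onset
  resistance estimate. Without the guaranteed hold, chronically short
  breaths never expose a plateau, the estimates go stale, and
  high-resistance cases destabilise. Note the compliance estimator uses
  the pressure the breath *started* from, not the end-expiratory pressure:
  the two differ whenever PEEP is still settling, and using the latter
  feeds the planner a wrong compliance.
* **Lung-pressure estimation during exhalation.** No flow crosses the
  internal connector pathway during exhalation, so the manifold sensor
  reads the connector pressure and `p_lung = p_sys + R_air q_E` with `q_E`
  itself computed from `p_sys` through the exhalation power law. `R_air`
  is estimated at the exhalation onset, when the lung is still at the
  plateau. The estimator defaults to the parabolic form
  (`drop = k q_E²`), matching the orifice-plate test lungs; the linear
  onset-ratio form over-predicts the drop at decaying flows and would
  close D too early, undershooting PEEP.
* **PEEP margin.** D closes when the estimated lung pressure reaches
  PEEP + 1 cmH2O. The margin implements the never-below-PEEP requirement;
  achieved PEEP consequently sits ~1 cmH2O above target, well inside the
  ±2 cmH2O band.
* **Peak-pressure alarm.** If the estimated connector pressure exceeds the
  alarm threshold (default 45 cmH2O) the controller enters the safe state
  (C closed, D open) and — the regulated part — *backs the reservoir
  target off* in proportion to the overshoot. Treating an alarm-aborted
  breath as a volume shortfall would raise the target and produce a
  runaway. For valve design-space sweeps the alarm is disabled by default:
  the sweep characterises the plant (oversized inhalation valves spike the
  connector pressure transiently), while the safety system is a property
  of the armed device.
* **Oxygen mixing.** The O2/air split solves the one-breath mole balance
  `δp_O2 = (F_t p₁ − F_prev p₀ − 0.21(p₁−p₀))/(1−0.21)`, clamped to the
  available rise; an unreachable FiO2 (large upward step into a full
  reservoir) converges over a few breaths. The sensed delivered fraction
  is used as `F_prev`, so the split is self-correcting.

## The engine

The only dynamic states are the reservoir pressure and composition and the
lung compartment volumes; there is no inertance. Each fixed step
(`dt = 0.5 ms` by default) the instantaneous flows are resolved
*algebraically*: a monotone scalar residual in the connector pressure is
bisected (60 iterations) to balance the valve-C power law, the connector
pathway drop and the compartment airway flows (or, during exhalation, the
compartment outflows against the valve-D power law), after which the states
are updated explicitly. The scheme is therefore quasi-static-exact up to
the step size; halving `dt` moves sampled pressures by well under 0.5 %,
and the module-level stepped free exhalation matches the closed-form
exponential to 1 % at `dt = 0.5 ms`. A stability guard aborts with a
diagnostic naming `dt` if any compartment flow exceeds 50 l/s. The
controller ticks every 5 ms by default (configurable up to the 20 ms of a
slower software stack; the ISO tolerance checks pass at both). Traces are
sampled at 200 Hz. Optional Gaussian sensor noise (seeded) perturbs the
controller inputs and the recorded sensor channels; it is off by default
and every run is reproducible from its configuration and seed.

The per-step scheduler embedded in the compiled engine is the same logic as
the exported `controller_tick()`; the R function is the testable
specification of one tick, and the test suite cross-checks engine behaviour
against the R-level formulas (delivered-volume agreement, estimator
consistency, mass balance).

## Study conditions and what the checks do (and do not) show

The simulated experiment suites are generated in code and mirror the bench
protocols: a 3⁵ factorial of clinical settings (243 cases, screened by the
ideal-lung peak-pressure estimate at 45 cmH2O against the R20/C20 reference
lung); the eight-row ISO 80601-2-12 table with its blank-cell inheritance
convention, Tests 1–2 built as genuine two-lung parallel assemblies; valve
Kv sweeps on 0.01-step grids (inlets 0.01–0.20, inhalation 0.02–0.80,
exhalation 0.10–0.80) with 20 breaths per case and breaths 6+ analysed; and
a long-duration run (R20/C25, VT 400, RR 30, PEEP 5, I:E 1:2, FiO2 21 %)
with 30 s snapshots every 10 min, desk-scaled to ~2 h, the first 30 breaths
(cold-start adaptation) excluded from the drift fit. ISO runs simulate
40 breaths and analyse breaths 6–36. Runs start directly at the case
settings rather than switching from the Default condition; the analysis
window discards the transition either way.

Pass bands are the ISO tolerances: tidal volume within ±(4 ml + 15 %),
PEEP within ±2 cmH2O, FiO2 within ±5 % of target.

What the passing tests show is that the *model* of the circuit, lung and
controller meets those bands and reproduces the design-space boundaries of
the published numerical model to about one grid step on the inlet (4 bar)
and inhalation valves. They do not validate against hardware: the gas is
ideal and isothermal, valve transients and compressible (choked) inlet flow
are not modelled (at a 4 bar supply a real inlet valve chokes; the
incompressible power law overestimates its flow at low supply pressures,
which shifts the 1.3 bar inlet boundary), the exhalation pathway exponent
is fixed at 0.5 in the absence of the calibrated values, humidification and
gas exchange are absent, and the test lungs are the only "patients" —
constant-parameter R-C compartments, with no inertance, nonlinear
elastance, recruitment or spontaneous effort. The exhalation-valve
usable-range boundary is particularly sensitive to the low-pressure
conductance of the exhalation pathway: with the default calibration it
lands at Kv_D ≈ 0.34, about 17 % above the published 0.29, driven by the
high-compliance parallel-lung case whose stacked mass-balance equilibrium
needs `a_E √p̄ T_ex ≥ V_T`.

## Numerical details worth knowing

* Pressures cross module boundaries in clinical units (cmH2O gauge,
  1 cmH2O = 98.0665 Pa, P_atm = 101325 Pa); the engine computes in pascal
  absolute and litres.
* Degenerate inputs: zero-breath runs return empty traces; breath
  segmentation needs two valve-C rising edges and warns otherwise; a
  demanded reservoir discharge below atmospheric is truncated with a
  warning; compartment volume is clamped at zero.
* Bland–Altman limits are two-sided at ±2 SD (not 1.96), with a
  zero-intercept-free linear fit of differences on means and a t-test on
  the slope; degenerate inputs (all means equal) are flagged rather than
  fitted.
* Tie-breaks: if delivery completes exactly at the hold boundary the
  breath is not flagged short; the alarm check precedes the
  volume-complete check within a tick.
* Problem sizes were chosen so the whole test suite and the full
  design-space sweeps each run in minutes on one CPU: 20-breath sweep
  runs, 40-breath ISO runs, a 2 h durability horizon. Longer horizons
  change none of the reported statistics in the deterministic setting.
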