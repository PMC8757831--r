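# Default run configuration: the ISO 80601-2-12 "Default" condition on an
# R20/C20 test lung with 4 bar gauge supplies and prototype valve sizes.
schema_version: 1
circuit:
  kv_a: 0.12
  kv_b: 0.12
  kv_c: 0.17
  kv_d: 0.70
  kv_s: 1.0
  supply_air_bar_gauge: 4
  supply_o2_bar_gauge: 4
  reservoir_volume_l: 2
lung:
  label: R20/C20
  v0_ml: 1000
  resistance_model: parabolic
settings:
  vt_ml: 400
  rr_bpm: 15
  peep_cmh2o: 5
  ie: "1:3"
  fio2_pct: 30
  alarm_pip_cmh2o: 45
sim:
  dt_ms: 0.5
  control_period_ms: 5
  sample_rate_hz: 200
  n_breaths: 20
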