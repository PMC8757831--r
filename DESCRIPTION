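Package: onoffvent
Title: Desk-Scale Simulation of an On-Off Solenoid Valve PRVC Ventilator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministic lumped-parameter simulator of a pressure-regulated
    volume control (PRVC) ventilator built entirely from on-off (2/2) solenoid
    valves, a two-litre mixing reservoir and two pressure sensors. Implements
    the pneumatic circuit (calibrated power-law flow pathways, ideal-gas
    reservoir, gas supplies), single- and two-compartment test-lung mechanics
    with orifice-plate parabolic resistance and volume-limited compliance, the
    six-phase timing controller with breath-to-breath reservoir-pressure
    adaptation and oxygen mixing, ISO 80601-2-12 breath metrics (tidal volume,
    PEEP, respiratory rate, FiO2, peak and plateau pressures, expiratory decay
    fraction), Bland-Altman agreement statistics, and the experiment protocols
    used to establish usable valve flow-coefficient ranges: a 243-case
    parametric sweep, the ISO 80601-2-12 test suite, valve Kv design-space
    sweeps and a long-duration drift check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
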