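# PRVC controller: settings, breath planning, estimators, valve scheduling.

test_that("settings derive the timing split from RR and I:E", {
  s <- vent_settings(500, 20, 5, "1:2", 0.3)
  expect_equal(s$t_in_s, 1)
  expect_equal(s$t_ex_s, 2)
  expect_equal(s$t_in_s + s$t_ex_s, 60 / 20)
  expect_equal(s$q_bar_ls, 0.5)
  s2 <- vent_settings(400, 15, 5, "1:3")
  expect_equal(s2$t_in_s, 1)
  expect_error(vent_settings(100, 15, 5), "vt_ml")
  expect_error(vent_settings(400, 50, 5), "rr_bpm")
  expect_error(vent_settings(400, 15, 5, "2:1"), "malformed|E")
  expect_error(parse_ie("banana"), "malformed")
  expect_equal(parse_ie(2.5), 2.5)
})

test_that("peak-pressure estimate is PEEP + VT/C + R*qbar", {
  s <- vent_settings(400, 15, 5, "1:3") # T_in = 1, qbar = 0.4
  expect_equal(estimate_pip(s, 20, 20), 5 + 20 + 8)
  s1 <- vent_settings(400, 15, 5, "1:3")
  s1$vt_ml <- 0
  s1$q_bar_ls <- 0
  expect_equal(estimate_pip(s1, 20, 20), 5) # degenerate
  # direct arithmetic: PEEP 5, VT 400, C 20, R 20, T_in 1 -> 33
  expect_equal(estimate_pip(vent_settings(400, 15, 5, "1:3"), 20, 20), 33)
})

test_that("screening keeps exactly the cases under the PiP limit", {
  cases <- parametric_sweep_cases()
  lung <- parse_lung("R20/C20")
  kept <- screen_sweep_cases(cases, lung, 45)
  # independent brute-force enumeration of Eq.-6 arithmetic
  n_oracle <- 0L
  for (vt in c(200, 400, 600)) for (rr in c(10, 20, 35))
    for (peep in c(5, 10, 15)) for (e in c(1, 2, 4))
      for (f in c(60, 75, 90)) {
        t_in <- 60 / rr / (1 + e)
        pip <- peep + vt / 20 + 20 * (vt / 1000 / t_in)
        if (pip <= 45) n_oracle <- n_oracle + 1L
      }
  expect_equal(nrow(kept), n_oracle)
  expect_gt(n_oracle, 0)
  expect_lt(n_oracle, 243)
  # an infinite limit keeps everything, order preserved
  all_kept <- screen_sweep_cases(cases, lung, Inf)
  expect_equal(nrow(all_kept), 243)
  expect_equal(all_kept$vt_ml, cases$vt_ml)
})

test_that("breath plan solves the oxygen/air mole balance", {
  s <- vent_settings(400, 15, 5, "1:3", 0.30)
  res <- reservoir(2, 0, o2_fraction = 0.21)
  res$pressure_abs_pa <- 1.013e5
  pl <- plan_breath(s, res, relief_bar_gauge = 10) # no clamping
  p1 <- pl$p_res_target_pa
  dpo2 <- pl$o2_share_pa
  # oracle: charge p0 -> p0 + dpo2 with pure O2, then air to p1; the
  # resulting fraction must equal the FiO2 target
  f1 <- (0.21 * 1.013e5 + 1.0 * dpo2 + 0.21 * (p1 - 1.013e5 - dpo2)) / p1
  expect_equal(f1, 0.30, tolerance = 1e-9)
  expect_equal(pl$o2_share_pa + pl$air_share_pa, p1 - 1.013e5)
  expect_false(pl$fio2_clamped)
})

test_that("breath plan clamps unreachable FiO2 and fixes pure-gas cases", {
  res <- reservoir(2, 0, o2_fraction = 0.21)
  res$pressure_abs_pa <- 1.013e5
  # air target with an air-filled reservoir: no oxygen share
  pl_air <- plan_breath(vent_settings(400, 15, 5, "1:3", 0.21), res)
  expect_equal(pl_air$o2_share_pa, 0)
  # FiO2 0.60 in a single 0.203-bar recharge of an air reservoir is
  # unreachable: the mole balance wants 0.600 bar of O2, clamped to the rise
  s60 <- vent_settings(400, 15, 5, "1:3", 0.60)
  res2 <- res
  pl <- plan_breath(s60, res2, relief_bar_gauge = 10)
  rise <- pl$p_res_target_pa - res2$pressure_abs_pa
  unclamped <- (0.60 * pl$p_res_target_pa - 0.21 * res2$pressure_abs_pa -
                  0.21 * rise) / 0.79
  if (unclamped > rise) {
    expect_true(pl$fio2_clamped)
    expect_equal(pl$o2_share_pa, rise)
  }
  # pure O2 from an O2-filled reservoir: no air share
  res3 <- reservoir(2, 0, o2_fraction = 1)
  res3$pressure_abs_pa <- 1.013e5
  pl_o2 <- plan_breath(vent_settings(400, 15, 5, "1:3", 1.0), res3)
  expect_equal(pl_o2$air_share_pa, 0, tolerance = 1e-9)
})

test_that("PRVC adaptation raises the target after a short breath", {
  s <- vent_settings(400, 15, 5, "1:3", 0.21)
  res <- reservoir(2, 0.05)
  last_full <- list(c_est = 20, r_est = 20, v_t_delivered = 400)
  last_short <- list(c_est = 20, r_est = 20, v_t_delivered = 300)
  pl_full <- plan_breath(s, res, last_full)
  pl_short <- plan_breath(s, res, last_short)
  expect_gt(pl_short$p_res_target_pa, pl_full$p_res_target_pa)
  expect_equal(pl_short$correction_pa, 0.7 * 0.1 * 101325 / 2,
               tolerance = 1e-9)
  # clamped at the relief ceiling
  pl_cap <- plan_breath(s, res, list(c_est = 20, r_est = 20,
                                     v_t_delivered = 0),
                        correction_pa = 5e5, relief_bar_gauge = 1)
  expect_lte(pl_cap$p_res_target_pa, 101325 + 1e5)
})

test_that("airway resistance is recovered from exhalation waveforms", {
  # direct arithmetic at the onset sample
  w <- data.frame(time = 0, p_sys = 15, q_e = 0.5)
  expect_equal(as.numeric(estimate_r_air(w, p_plat = 25)), 20)
  # zero-flow window returns the previous estimate, flagged stale
  w0 <- data.frame(time = 0:3 / 200, p_sys = c(5, 5, 5, 5), q_e = rep(0, 4))
  est <- estimate_r_air(w0, p_plat = 25, previous = 17)
  expect_equal(as.numeric(est), 17)
  expect_true(attr(est, "stale"))
  # synthetic exponential decay with known linear R: recovered within 5%
  r_true <- 30
  c_lung <- 20
  tau <- r_true * c_lung / 1000
  tt <- seq(0, 0.1, by = 1 / 200)
  p_lung <- 5 + 25 * exp(-tt / tau)
  q_e <- 25 / tau * exp(-tt / tau) * c_lung / 1000
  w2 <- data.frame(time = tt, p_sys = p_lung - r_true * q_e, q_e = q_e)
  # onset ratio is exact on the noise-free closed form
  expect_equal(as.numeric(estimate_r_air(w2, p_plat = 30)), r_true)
  # least-squares refinement over a short early window stays within 5%
  # (the lung pressure decays through the window, biasing longer fits)
  est2 <- estimate_r_air(w2, p_plat = 30, refine_ms = 30)
  expect_lt(abs(as.numeric(est2) - r_true) / r_true, 0.05)
})

test_that("exhalation lung-pressure estimate adds the resistive drop", {
  expect_equal(estimate_p_lung_exhale(5, 0, 20, model = "linear"), 5)
  expect_equal(estimate_p_lung_exhale(8, 0.25, 20, model = "linear"), 13)
  # parabolic variant anchored at the onset flow
  expect_equal(estimate_p_lung_exhale(8, 0.5, 20, model = "parabolic",
                                      q_ref_ls = 0.5), 18)
  expect_gte(estimate_p_lung_exhale(8, 0.3, 20), 8)
  expect_error(estimate_p_lung_exhale(8, -1, 20), "q_e")
})

test_that("the exhalation estimator tracks the engine's true lung pressure", {
  tr <- simulate_ventilation(sim = quick_sim(8))
  seg <- segment_breaths(tr)
  i <- which(seg$breath == 6)
  sl <- tr[seg$i_start[i]:seg$i_end[i], ]
  exh <- sl[as.logical(sl$valve_d) & sl$q_e / 60 > 0.05, ]
  # with the exact orifice-plate coefficient (R20 rated at 60 l/min:
  # k = 20 cmH2O/(l/s)^2) the estimate reproduces the true lung pressure
  est <- estimate_p_lung_exhale(exh$p_sys, exh$q_e / 60, 20,
                                model = "parabolic", q_ref_ls = 1)
  rel <- abs(est - exh$p_lung) / exh$p_lung
  expect_lt(max(rel), 0.10)
})

test_that("controller tick schedules the valves through the breath", {
  circ <- ventilator_circuit()
  s <- vent_settings(400, 15, 5, "1:3", 0.5)
  plan <- list(p_res_target_pa = 101325 + 35000, o2_share_pa = 12000,
               air_share_pa = 23000)
  st <- controller_state(t_start = 0, plan = plan)
  # phase 1: C open, integrating delivered volume from the pressure pair
  out <- controller_tick(st, list(p_res_pa = 101325 + 30000,
                                  p_sys_cmh2o = 10), 0.005, s, circ)
  expect_true(out$commands[["C"]])
  expect_gt(out$state$delivered_ml, 0)
  # C closes the tick delivered volume reaches VT
  st2 <- out$state
  st2$delivered_ml <- 400
  out2 <- controller_tick(st2, list(p_res_pa = 101325 + 30000,
                                    p_sys_cmh2o = 10), 0.010, s, circ)
  expect_false(out2$commands[["C"]])
  # at T_in, D opens and the oxygen charge (A) starts
  st3 <- out2$state
  out3 <- controller_tick(st3, list(p_res_pa = 101325 + 5000,
                                    p_sys_cmh2o = 25), s$t_in_s, s, circ)
  expect_true(out3$commands[["D"]])
  expect_true(out3$commands[["A"]])
  expect_false(out3$commands[["C"]])
  # A hands over to B once the O2 share of the rise is charged
  st4 <- out3$state
  out4 <- controller_tick(st4, list(p_res_pa = 101325 + 5000 + 12500,
                                    p_sys_cmh2o = 20), s$t_in_s + 0.005, s,
                          circ)
  expect_false(out4$commands[["A"]])
  expect_true(out4$commands[["B"]])
  # D closes when the estimated lung pressure reaches PEEP + margin
  st5 <- out4$state
  st5$onset_done <- TRUE
  st5$k_est <- 20
  out5 <- controller_tick(st5, list(p_res_pa = 101325 + 20000,
                                    p_sys_cmh2o = 4.0),
                          s$t_in_s + 0.5, s, circ)
  expect_false(out5$commands[["D"]])
  # hard cutoff: C never survives past T_in even when short
  st6 <- controller_state(t_start = 0, plan = plan)
  out6 <- controller_tick(st6, list(p_res_pa = 101325 + 300,
                                    p_sys_cmh2o = 5), s$t_in_s, s, circ)
  expect_false(out6$commands[["C"]])
  expect_true(out6$state$short)
})

test_that("alarm drives the safe state: C closed, D open", {
  circ <- ventilator_circuit()
  s <- vent_settings(400, 15, 5, "1:3", 0.21, alarm_pip_cmh2o = 45)
  st <- controller_state(t_start = 0,
                         plan = list(p_res_target_pa = 2e5,
                                     o2_share_pa = 0, air_share_pa = 0))
  out <- controller_tick(st, list(p_res_pa = 101325 + 90000,
                                  p_sys_cmh2o = 80), 0.005, s, circ)
  expect_false(out$commands[["C"]])
  expect_true(out$commands[["D"]])
  expect_true(out$state$alarm)
})
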