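# Fixed-step engine: determinism, conservation, convergence, PRVC dynamics.

test_that("runs are deterministic and an empty run yields an empty trace", {
  a <- simulate_ventilation(sim = quick_sim(4))
  b <- simulate_ventilation(sim = quick_sim(4))
  expect_identical(as.data.frame(a), as.data.frame(b))
  e <- simulate_ventilation(sim = quick_sim(0))
  expect_equal(nrow(e), 0)
  expect_warning(me <- breath_metrics(e), "rising edges")
  expect_equal(nrow(me), 0)
})

test_that("gas is conserved to within 1e-6 relative", {
  sim <- quick_sim(10, precharge = FALSE)
  tr <- simulate_ventilation(ventilator_circuit(), "R20/C20",
                             default_settings(), sim,
                             init = list(p_res_abs = 101325 + 30000,
                                         f_res = 0.21))
  ga <- gas_accounting(tr)
  fs <- final_state(tr)
  supplied <- ga$in_o2_l + ga$in_air_l
  vented <- ga$exhaled_l + ga$relief_vented_l
  d_res <- (fs$p_res_abs - (101325 + 30000)) * 2 / 101325
  d_lung <- (sum(fs$v_ml) - 20 * 5) / 1000
  resid <- supplied - vented - (d_res + d_lung)
  expect_lt(abs(resid) / supplied, 1e-6)
  # and the lung-side balance on its own
  expect_lt(abs(ga$delivered_l - ga$exhaled_l - d_lung) /
              max(ga$delivered_l, 1e-9), 1e-6)
})

test_that("no sample carries simultaneous inhaled and exhaled flow", {
  tr <- simulate_ventilation(sim = quick_sim(6))
  expect_true(all(tr$q_i * tr$q_e == 0))
  expect_true(all(tr$q_i >= 0))
  expect_true(all(tr$q_e >= 0))
})

test_that("inhalation valve C is closed by T_in, and inlet valves never
           overlap C (charging confined to the exhalation phase)", {
  # undersized Kv_C forces delivery to run the whole inspiratory window
  circ <- with_kv(ventilator_circuit(), "c", 0.05)
  tr <- simulate_ventilation(circ, "R20/C20", default_settings(),
                             quick_sim(6))
  s <- attr(tr, "settings")
  seg <- segment_breaths(tr)
  for (i in seq_len(nrow(seg))) {
    sl <- tr[seg$i_start[i]:seg$i_end[i], ]
    tb <- sl$time - seg$t_start[i]
    expect_lte(max(tb[as.logical(sl$valve_c)]), s$t_in_s + 0.006)
  }
  expect_false(any(tr$valve_c & (tr$valve_a | tr$valve_b)))
  # short breaths are flagged and the adaptation raises the next target
  bl <- breath_log(tr)
  expect_true(any(bl$short == 1))
})

test_that("flow-sensorless volume agrees with the true lung volume gain", {
  tr <- simulate_ventilation(sim = quick_sim(10))
  bl <- breath_log(tr)
  steady <- bl[bl$breath >= 5, ]
  rel <- abs(steady$delivered_ml - steady$delivered_true_ml) /
    steady$delivered_true_ml
  expect_lt(max(rel), 0.02)
  # per-breath mass sanity: integrated inflow equals the volume gain
  seg <- segment_breaths(tr)
  for (i in 5:nrow(seg)) {
    sl <- tr[seg$i_start[i]:seg$i_end[i], ]
    gain <- max(sl$v_lung_ml) - sl$v_lung_ml[1]
    expect_lt(abs(bl$delivered_true_ml[i] - gain), 1.5)
  }
})

test_that("halving the step changes sampled pressures by less than 0.5%", {
  s <- default_settings()
  tr1 <- simulate_ventilation(ventilator_circuit(), "R20/C20", s,
                              quick_sim(6, dt_s = 5e-4))
  tr2 <- simulate_ventilation(ventilator_circuit(), "R20/C20", s,
                              quick_sim(6, dt_s = 2.5e-4))
  n <- min(nrow(tr1), nrow(tr2))
  scale <- max(tr1$p_sys)
  for (v in c("p_sys", "p_lung", "p_res")) {
    d <- abs(tr1[[v]][1:n] - tr2[[v]][1:n]) / max(tr1[[v]], scale)
    expect_lt(max(d), 0.005)
  }
})

test_that("PRVC re-converges within 6 breaths of a compliance step", {
  band <- function(vt, target) abs(vt - target) <= 4 + 0.15 * target
  warm <- simulate_ventilation(lung = "R20/C20",
                               settings = default_settings(),
                               sim = quick_sim(12))
  for (c_new in c(15, 30)) {
    stepped <- simulate_ventilation(
      lung = lung_compartment(20, c_new),
      settings = default_settings(),
      sim = quick_sim(10, precharge = FALSE),
      init = final_state(warm)
    )
    m <- breath_metrics(stepped)
    expect_true(all(band(m$v_t_delivered[m$breath %in% 6:9], 400)),
                label = sprintf("VT in band within 6 breaths of C -> %g",
                                c_new))
  }
})

test_that("delivered FiO2 reaches a new set point within 10 breaths", {
  warm <- simulate_ventilation(settings = vent_settings(400, 15, 5, "1:3",
                                                        0.21),
                               sim = quick_sim(10))
  stepped <- simulate_ventilation(
    settings = vent_settings(400, 15, 5, "1:3", 0.60),
    sim = quick_sim(12, precharge = FALSE),
    init = final_state(warm)
  )
  m <- breath_metrics(stepped)
  late <- m$fio2_measured[m$breath %in% 10:11]
  expect_true(all(abs(late - 0.60) / 0.60 <= 0.05))
})

test_that("achieved PEEP never undershoots the target (noise-free floor)", {
  suite <- run_iso_suite(sim = quick_sim(14), window = 6:13)
  expect_true(all(suite$peep_achieved >= suite$peep_target - 0.2))
})

test_that("seeded sensor noise keeps metrics inside the ISO bands", {
  noisy <- quick_sim(16, sensor_noise = list(pressure_cmh2o = 0.3,
                                             o2 = 0.005), seed = 42)
  tr <- simulate_ventilation(sim = noisy)
  m <- breath_metrics(tr)
  m <- m[m$breath %in% 6:15, ]
  expect_true(all(abs(m$v_t_delivered - 400) <= 4 + 0.15 * 400))
  expect_true(all(abs(m$peep_achieved - 5) <= 2))
  # reproducible under the same seed
  tr2 <- simulate_ventilation(sim = noisy)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
})

test_that("long runs stream snapshots with bounded memory and no drift", {
  out <- run_durability(total_hours = 0.75)
  expect_gte(nrow(out$snapshots), 3)
  expect_true(all(out$snapshots$n_breaths >= 10))
  expect_true(all(out$drift$r_squared < 0.05))
  expect_true(all(abs(out$snapshots$peep_achieved - 5) <= 2))
  # snapshots reproduce plain steady-state run metrics
  p <- durability_protocol()
  tr <- simulate_ventilation(ventilator_circuit(), p$lung, p$settings,
                             quick_sim(30))
  m <- breath_metrics(tr)
  first <- out$snapshots$v_t_delivered[1]
  expect_lt(abs(first - mean(m$v_t_delivered[m$breath %in% 25:29])), 12)
})
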