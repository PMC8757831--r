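# Experiment protocols: factorial sweep, ISO suite, Kv sweeps, durability.

test_that("the parametric factorial enumerates all 243 cases", {
  cases <- parametric_sweep_cases()
  expect_equal(nrow(cases), 243)
  expect_equal(nrow(unique(cases)), 243)
  expect_setequal(unique(cases$vt_ml), c(200, 400, 600))
  expect_setequal(unique(cases$fio2_pct), c(60, 75, 90))
  expect_setequal(unique(cases$ie), c("1:1", "1:2", "1:4"))
})

test_that("ISO suite resolves blank-cell inheritance with no gaps", {
  suite <- iso_suite()
  expect_equal(nrow(suite), 8)
  expect_false(anyNA(suite))
  t5 <- suite[suite$id == "5", ]
  expect_equal(t5$vt_ml, 300)
  t4 <- suite[suite$id == "4", ]
  expect_equal(t4$vt_ml, 500) # inherited via Test 3 <- Test 1
  expect_equal(t4$rr_bpm, 20)
  expect_equal(t4$ie, "1:2")
  expect_equal(t4$c, 20)
  t3 <- suite[suite$id == "3", ]
  expect_equal(t3$fio2_pct, 90) # inherited from Test 2
  # inheritance is idempotent: re-filling changes nothing
  refilled <- tidyr::fill(suite, dplyr::everything(), .direction = "down")
  expect_identical(as.data.frame(refilled), as.data.frame(suite))
  # derived timing is consistent with the printed 1 s inspiration
  for (i in seq_len(nrow(suite))) {
    expect_equal(iso_settings(suite[i, ])$t_in_s, 1, tolerance = 1e-9)
  }
})

test_that("Tests 1-2 build two-compartment parallel assemblies", {
  suite <- iso_suite()
  a1 <- iso_lung(suite[suite$id == "1", ])
  expect_length(a1$compartments, 2)
  expect_equal(a1$compartments[[2]]$r_rated, 5)
  a2 <- iso_lung(suite[suite$id == "2", ])
  expect_equal(a2$compartments[[2]]$r_rated, 20)
  expect_equal(a2$compartments[[1]]$c_lung, 25)
  a7 <- iso_lung(suite[suite$id == "7", ])
  expect_length(a7$compartments, 1)
  expect_equal(a7$compartments[[1]]$c_lung, 10)
})

test_that("kv threshold extraction picks boundaries from a pass/fail map", {
  fake <- tibble::tibble(
    kv = rep(c(0.1, 0.2, 0.3, 0.4), each = 2),
    id = rep(c("a", "b"), 4),
    pass = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  expect_equal(kv_threshold(fake, "smallest_pass_all"), 0.3)
  expect_equal(kv_threshold(fake, "largest_fail_any"), 0.2)
  all_pass <- transform(fake, pass = TRUE)
  expect_true(is.na(kv_threshold(all_pass, "largest_fail_any")))
  expect_error(kv_sweep("c", c(0.2, 0.1)), "increasing")
})

test_that("oversized valves pass and VT is monotone in Kv_C", {
  sim <- quick_sim(12)
  suite <- iso_suite()[c(1, 6), ] # Default + Test 5 (single lungs, fast)
  sw <- kv_sweep("c", c(0.05, 0.10, 0.17, 0.40), suite = suite, sim = sim,
                 fail_fast = FALSE)
  by_case <- split(sw, sw$id)
  for (b in by_case) {
    v <- b$v_t_delivered[order(b$kv)]
    # non-decreasing up to the controller's one-tick closing granularity
    expect_true(all(diff(v) > -12))
    expect_gt(v[length(v)], v[1])
  }
  big <- sw[sw$kv == 0.40, ]
  expect_true(all(big$pass))
})

test_that("inlet and exhalation sweeps are monotone on the default suite", {
  sim <- quick_sim(12)
  suite <- iso_suite()[c(1, 6), ]
  ab <- kv_sweep("ab", c(0.01, 0.02, 0.06, 0.12), suite = suite, sim = sim,
                 fail_fast = FALSE)
  per <- dplyr::summarise(dplyr::group_by(ab, kv), ok = all(pass),
                          .groups = "drop")
  expect_true(all(diff(per$ok[order(per$kv)]) >= 0)) # pass never reverts
  d <- kv_sweep("d", c(0.15, 0.30, 0.70), suite = suite, sim = sim,
                fail_fast = FALSE)
  perd <- dplyr::summarise(dplyr::group_by(d, kv), ok = all(pass),
                           .groups = "drop")
  expect_true(all(diff(perd$ok[order(perd$kv)]) >= 0))
})

test_that("durability protocol echoes the long-run settings", {
  p <- durability_protocol()
  expect_equal(p$settings$vt_ml, 400)
  expect_equal(p$settings$rr_bpm, 30)
  expect_equal(p$settings$peep_cmh2o, 5)
  expect_equal(p$settings$e_ratio, 2)
  expect_equal(p$settings$fio2, 0.21)
  expect_equal(p$lung, "R20/C25")
  expect_equal(p$snapshot_every_s, 600)
  expect_equal(p$snapshot_len_s, 30)
})

test_that("a small screened parametric sweep hits its targets", {
  cases <- screen_sweep_cases(parametric_sweep_cases(), "R20/C20", 45)
  picks <- cases[c(1, nrow(cases) %/% 2, nrow(cases)), ]
  out <- run_parametric_sweep(picks, sim = quick_sim(12), window = 7:11)
  expect_equal(nrow(out), 3)
  expect_true(all(out$pass_vt))
  expect_true(all(abs(out$peep_achieved - out$peep_target) <= 2))
  expect_true(all(abs(out$fio2_measured - out$fio2_target) /
                    out$fio2_target <= 0.05))
})

test_that("supply and valve helpers modify the circuit in place", {
  c13 <- with_supplies(ventilator_circuit(), 1.3)
  expect_equal(c13$supply_air$pressure_bar_gauge, 1.3)
  expect_equal(c13$supply_o2$pressure_bar_gauge, 1.3)
  expect_equal(c13$supply_o2$o2_fraction, 1)
  cab <- with_kv(ventilator_circuit(), "ab", 0.05)
  expect_equal(cab$valves$A$kv, 0.05)
  expect_equal(cab$valves$B$kv, 0.05)
  expect_equal(cab$valves$C$kv, 0.17)
})
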