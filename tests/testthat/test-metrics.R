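# Breath segmentation, ISO metric extraction, Bland-Altman statistics.

synthetic_breath <- function() {
  # one complete breath at 200 Hz: constant 0.4 l/s inspiration for 1 s,
  # exhalation for 2 s, next breath starting at t = 3
  t <- seq(0, 3.2, by = 0.005)
  valve_c <- t < 1 | t >= 3
  valve_d <- t >= 1 & t < 2
  q_i <- ifelse(valve_c, 24, 0)
  p_sys <- ifelse(t < 1, 20, ifelse(t < 2, 10, 5))
  data.frame(time = t, valve_c = valve_c, valve_d = valve_d,
             q_i = q_i, q_e = ifelse(valve_d, 12, 0),
             p_sys = p_sys, p_conn = p_sys, p_lung = p_sys,
             o2_delivered = 0.6, phase = 1)
}

test_that("breaths are delimited by Valve C rising edges", {
  t <- seq(0, 8, by = 0.005)
  df <- data.frame(time = t, valve_c = (t %% 3) < 1)
  seg <- segment_breaths(df)
  expect_equal(nrow(seg), 2)
  expect_equal(60 / diff(seg$t_start[1:2]), 20) # RR = 20 bpm
  # constant-closed C yields no breaths, with a warning
  df$valve_c <- FALSE
  expect_warning(seg0 <- segment_breaths(df), "rising edges")
  expect_equal(nrow(seg0), 0)
})

test_that("tidal volume is the trapezoidal integral of inhaled flow", {
  t <- seq(0, 1, by = 0.005)
  expect_equal(tidal_volume(data.frame(time = t, q_i = 24)), 400)
  expect_equal(tidal_volume(data.frame(time = t, q_i = 0)), 0)
  # triangular ramp 0 -> 48 l/min over 1 s has area 400 ml
  expect_equal(tidal_volume(data.frame(time = t, q_i = 48 * t)), 400)
  # linear in flow scaling
  sl <- data.frame(time = t, q_i = 10 + 20 * t)
  expect_equal(tidal_volume(transform(sl, q_i = 3 * q_i)),
               3 * tidal_volume(sl))
})

test_that("achieved PEEP averages the last 50 ms of the exhalation", {
  t <- seq(0, 1, by = 0.005)
  expect_equal(peep_achieved(data.frame(time = t, p_sys = 5)), 5)
  # linear 6 -> 4 over the last 50 ms averages to the midpoint
  p <- ifelse(t < 0.95, 6, 6 - (t - 0.95) / 0.05 * 2)
  expect_equal(peep_achieved(data.frame(time = t, p_sys = p)), 5,
               tolerance = 0.06)
  # invariant to the tail length for constant tails
  t2 <- seq(0, 4, by = 0.005)
  expect_equal(peep_achieved(data.frame(time = t2, p_sys = 5)), 5)
})

test_that("FiO2 averages the oxygen signal over the exhalation", {
  sl <- synthetic_breath()
  expect_equal(fio2_measured(sl), 0.6)
  sl$o2_delivered <- 0.21
  expect_equal(fio2_measured(sl), 0.21)
})

test_that("Tex* is the D-open fraction of the expiratory time", {
  # breath slice [0, 3): D open 1 -> 2 s, expiration 1 -> 3 s
  sl <- synthetic_breath()
  sl <- sl[sl$time < 3, ]
  tx <- tex_star(sl)
  expect_equal(as.numeric(tx), 0.5, tolerance = 0.01)
  expect_false(attr(tx, "stacking"))
  # D never closing gives 1.0 with the stacking flag
  sl2 <- synthetic_breath()
  sl2 <- sl2[sl2$time < 3, ]
  sl2$valve_d <- sl2$time >= 1
  tx2 <- tex_star(sl2)
  expect_equal(as.numeric(tx2), 1)
  expect_true(attr(tx2, "stacking"))
})

test_that("metrics round-trip the engine's internal bookkeeping", {
  tr <- simulate_ventilation(sim = quick_sim(10))
  m <- breath_metrics(tr)
  bl <- breath_log(tr)
  steady <- m$breath >= 5
  # measured RR equals the programmed rate to the sampling grid
  expect_true(all(abs(m$rr_measured - 15) < 0.1))
  # trapezoidal VT vs controller-delivered volume: within one sample of flow
  expect_true(all(abs(m$v_t_delivered[steady] -
                        bl$delivered_true_ml[steady]) < 6))
  # compliance estimate recovers the configured lung at steady state
  expect_true(all(abs(m$c_est[m$breath >= 6] - 20) < 2))
  # ISO Test 2 expiratory-time denominator: RR 12, 1:4 -> T_ex = 4 s
  s2 <- vent_settings(500, 12, 10, "1:4", 0.9)
  expect_equal(s2$t_ex_s, 4)
})

test_that("Bland-Altman matches hand arithmetic and handles edge cases", {
  # identical pairs: zero difference everywhere
  ba0 <- suppressWarnings(bland_altman(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  # constant offset: mean 1, sd 0
  ba1 <- bland_altman(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ba1$mean_diff, 1)
  expect_equal(ba1$sd_diff, 0)
  expect_equal(ba1$loa_high - ba1$loa_low, 4 * ba1$sd_diff)
  # random pairs vs explicit closed-form arithmetic
  set.seed(7)
  x <- rnorm(25, 10, 2)
  y <- x + rnorm(25, 0.5, 0.3)
  ba <- bland_altman(x, y)
  d <- y - x
  m <- (x + y) / 2
  expect_equal(ba$mean_diff, sum(d) / 25)
  expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / 24))
  slope <- sum((m - mean(m)) * (d - mean(d))) / sum((m - mean(m))^2)
  expect_equal(ba$slope, slope)
  se <- sqrt(sum((d - mean(d) - slope * (m - mean(m)))^2) / 23 /
               sum((m - mean(m))^2))
  expect_equal(ba$slope_p, 2 * pt(abs(slope / se), 23, lower.tail = FALSE),
               tolerance = 1e-9)
  # degenerate means: slope undefined, flagged
  expect_warning(bad <- bland_altman(c(1, 1, 1), c(1, 1, 1)), "degenerate|equal")
  expect_true(bad$degenerate)
  expect_error(bland_altman(1:2, 1:2), "3")
  # tidy/glance expose the statistics
  expect_equal(glance(ba)$mean_diff, ba$mean_diff)
  expect_true("loa_high" %in% tidy(ba)$term)
})

test_that("flow decay fraction separates the inhalation regimes", {
  # synthetic: flow falling linearly 60 -> 24 l/min during inspiration
  t <- seq(0, 3.2, by = 0.005)
  vc <- t < 1 | t >= 3
  df <- data.frame(time = t, valve_c = vc, valve_d = t >= 1 & t < 2,
                   q_i = ifelse(t < 1, 60 - 36 * t, ifelse(t >= 3, 60, 0)),
                   q_e = 0, p_sys = 5, p_conn = 5, p_lung = 5,
                   o2_delivered = 0.21)
  expect_equal(flow_decay_fraction(df, 1), 100 * (60 - 24.06) / 60,
               tolerance = 0.2)
})
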