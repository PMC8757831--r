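# Per-breath ISO 80601-2-12 metric extraction from sampled waveform traces,
# plus Bland-Altman agreement statistics.

#' Segment a trace into breaths
#'
#' Breaths are delimited by consecutive rising edges of the Valve C signal
#' (the start of each inhalation); the respiratory rate is the reciprocal of
#' the edge spacing. Partial leading/trailing segments are discarded.
#'
#' @param trace a `vent_trace` (or any data frame with `time` and `valve_c`).
#' @return a tibble with one row per complete breath: `breath`, `t_start`,
#'   `t_end`, `i_start`, `i_end` (row indices into `trace`). Empty, with a
#'   warning, when fewer than two rising edges are present.
#' @export
segment_breaths <- function(trace) {
  stopifnot(all(c("time", "valve_c") %in% names(trace)))
  v <- as.logical(trace$valve_c)
  edges <- which(diff(c(FALSE, v)) == 1L)
  if (length(edges) < 2L) {
    warning("fewer than two Valve C rising edges: no complete breath",
            call. = FALSE)
    return(tibble::tibble(breath = integer(), t_start = numeric(),
                          t_end = numeric(), i_start = integer(),
                          i_end = integer()))
  }
  n <- length(edges) - 1L
  tibble::tibble(
    breath = seq_len(n),
    t_start = trace$time[edges[-length(edges)]],
    t_end = trace$time[edges[-1]],
    i_start = edges[-length(edges)],
    i_end = edges[-1] - 1L
  )
}

#' Trapezoidal tidal volume of a breath slice
#'
#' Integrates the inhaled flow `q_i` (l/min) over the slice with the
#' trapezoidal rule; returns ml.
#'
#' @param slice data frame with `time` and `q_i`.
#' @return tidal volume in ml.
#' @examples
#' tidal_volume(data.frame(time = seq(0, 1, 0.005), q_i = 24))
#' @export
tidal_volume <- function(slice) {
  if (nrow(slice) < 2L) return(0)
  trapz(slice$time, slice$q_i / 60 * 1000)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Achieved PEEP of a breath slice
#'
#' Mean system pressure over the last `window_ms` (default 50 ms, the ISO
#' 80601-2-12:2020 definition) of the exhalation phase, i.e. before the next
#' breath starts. A shorter available tail is used as-is with a warning.
#'
#' @param slice data frame with `time` and `p_sys` covering one breath.
#' @param window_ms averaging window, ms.
#' @return PEEP in cmH2O.
#' @export
peep_achieved <- function(slice, window_ms = 50) {
  t_end <- slice$time[nrow(slice)]
  sel <- slice$time > t_end - window_ms / 1000 - 1e-9
  if (slice$time[which(sel)[1]] > t_end - window_ms / 1000 + 2e-3 &&
      which(sel)[1] == 1L) {
    warning("exhalation shorter than the PEEP window; using available tail",
            call. = FALSE)
  }
  mean(slice$p_sys[sel])
}

#' Mean delivered oxygen fraction over the exhalation
#'
#' The oxygen sensor sits on the delivery manifold, so its reading during
#' each exhalation is the fraction of the breath just delivered.
#'
#' @param slice data frame with `time` and `o2_delivered`.
#' @param t3 exhalation start time; defaults to the first `valve_d` rising
#'   edge in the slice.
#' @return oxygen fraction.
#' @export
fio2_measured <- function(slice, t3 = NULL) {
  if (is.null(t3)) t3 <- d_edge_time(slice)
  if (is.na(t3)) return(mean(slice$o2_delivered))
  mean(slice$o2_delivered[slice$time >= t3 - 1e-9])
}

d_edge_time <- function(slice, falling = FALSE) {
  v <- as.logical(slice$valve_d)
  e <- if (falling) which(diff(c(v[1], v)) == -1L) else
    which(diff(c(FALSE, v)) == 1L)
  if (!length(e)) NA_real_ else slice$time[e[1]]
}

#' Fraction of the expiratory time used to reach PEEP
#'
#' `Tex* = (t6 - t3) / T_ex` where t3 is the Valve D opening (start of
#' exhalation, at T_in), t6 the Valve D closure (lung at PEEP) and
#' `T_ex = 60/RR * E/(1+E)` the allotted expiratory time (measured here as
#' the time from t3 to the next breath). Clipped to (0, 1]; if Valve D never
#' closes within the breath the value is 1 and the breath is flagged as
#' potential breath stacking.
#'
#' @param slice data frame covering one breath with `time` and `valve_d`.
#' @return Tex* in (0, 1] with attribute `stacking`.
#' @export
tex_star <- function(slice) {
  t3 <- d_edge_time(slice)
  t_end <- slice$time[nrow(slice)]
  if (is.na(t3) || t_end <= t3) {
    return(structure(NA_real_, stacking = NA))
  }
  t6 <- d_edge_time(slice, falling = TRUE)
  stacking <- is.na(t6)
  if (stacking) t6 <- t_end
  structure(min(max((t6 - t3) / (t_end - t3), 1e-12), 1), stacking = stacking)
}

#' Per-breath ISO metrics of a trace
#'
#' Computes, for every complete breath (see [segment_breaths()]): delivered
#' tidal volume (trapezoidal integral of the inhaled flow), achieved PEEP
#' (last-50-ms average), measured respiratory rate (Valve C edge spacing),
#' delivered FiO2 (exhalation average of the oxygen sensor), peak inspiratory
#' pressure (max connector pressure during inspiration), plateau pressure
#' (connector pressure at the last all-closed inspiration sample), Tex*, and
#' the derived compliance and resistance estimates
#' `c_est = V_T / (p_plat - PEEP)` and `r_est` from the exhalation onset.
#'
#' @param trace a `vent_trace` or a data frame in the engine trace schema.
#' @param breaths optional integer vector restricting which breaths to keep.
#' @return a tibble with one row per breath.
#' @export
breath_metrics <- function(trace, breaths = NULL) {
  seg <- segment_breaths(trace)
  if (!nrow(seg)) return(empty_metrics())
  out <- purrr::map_dfr(seq_len(nrow(seg)), function(i) {
    sl <- trace[seg$i_start[i]:seg$i_end[i], , drop = FALSE]
    t3 <- d_edge_time(sl)
    insp <- if (is.na(t3)) sl else sl[sl$time < t3, , drop = FALSE]
    phase2 <- insp[!as.logical(insp$valve_c), , drop = FALSE]
    p_plat <- if (nrow(phase2)) phase2$p_conn[nrow(phase2)] else
      insp$p_conn[nrow(insp)]
    peep <- peep_achieved(sl)
    vt <- tidal_volume(sl)
    tex <- tex_star(sl)
    # exhalation-onset resistance estimate
    exh <- sl[sl$time >= t3 & sl$q_e / 60 > 0.01, , drop = FALSE]
    r_est <- if (!is.na(t3) && nrow(exh)) {
      (p_plat - exh$p_sys[1]) / (exh$q_e[1] / 60)
    } else NA_real_
    tibble::tibble(
      breath = seg$breath[i],
      v_t_delivered = vt,
      peep_achieved = peep,
      rr_measured = 60 / (seg$t_end[i] - seg$t_start[i]),
      fio2_measured = fio2_measured(sl, t3),
      pip = max(insp$p_conn),
      p_plat = p_plat,
      tex_star = as.numeric(tex),
      stacking = isTRUE(attr(tex, "stacking")),
      c_est = if (p_plat - peep > 0.25) vt / (p_plat - peep) else NA_real_,
      r_est = r_est
    )
  })
  if (!is.null(breaths)) out <- out[out$breath %in% breaths, , drop = FALSE]
  out
}

empty_metrics <- function() {
  tibble::tibble(
    breath = integer(), v_t_delivered = numeric(), peep_achieved = numeric(),
    rr_measured = numeric(), fio2_measured = numeric(), pip = numeric(),
    p_plat = numeric(), tex_star = numeric(), stacking = logical(),
    c_est = numeric(), r_est = numeric()
  )
}

#' Relative inspiratory flow decay of a breath
#'
#' `100 * (q_initial - q_end) / q_initial`, where `q_initial` is the peak
#' early-inspiration flow and `q_end` the flow at the beginning of
#' expiration (the last sample before Valve C closes). Distinguishes the
#' three inhalation regimes: near zero for flow-limited (small Kv_C,
#' VCV-like) delivery, around 60% in the pressure-regulated medium regime,
#' and large with an early pressure spike for oversized valves.
#'
#' @param trace a `vent_trace`.
#' @param breath which breath to evaluate (default: last complete breath).
#' @return percentage decay.
#' @export
flow_decay_fraction <- function(trace, breath = NULL) {
  seg <- segment_breaths(trace)
  if (!nrow(seg)) stopf("no complete breath in trace")
  if (is.null(breath)) breath <- seg$breath[nrow(seg)]
  i <- match(breath, seg$breath)
  sl <- trace[seg$i_start[i]:seg$i_end[i], , drop = FALSE]
  insp <- sl[as.logical(sl$valve_c) & sl$q_i > 0, , drop = FALSE]
  if (nrow(insp) < 2L) stopf("no inspiratory flow in breath %d", breath)
  q0 <- max(insp$q_i)
  q1 <- insp$q_i[nrow(insp)]
  100 * (q0 - q1) / q0
}

#' Bland-Altman agreement analysis
#'
#' Differences `y - x` against means `(x + y)/2`: mean difference, standard
#' deviation, two-sided limits of agreement at +/- 2 SD, and a least-squares
#' regression of the differences on the means with a t-test on the slope
#' (proportional bias).
#'
#' @param x,y paired measurements (>= 3 pairs).
#' @return an object of class `vent_bland_altman` with [tidy()] and
#'   [glance()] methods.
#' @examples
#' ba <- bland_altman(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.3))
#' glance(ba)
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must be the same length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need at least 3 complete pairs")
  d <- y - x
  m <- (x + y) / 2
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  degenerate <- var(m) < 1e-12
  if (degenerate) {
    warning("all pair means equal: regression slope undefined", call. = FALSE)
    slope <- intercept <- r2 <- slope_p <- NA_real_
  } else {
    fit <- lm(d ~ m)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    sfit <- suppressWarnings(summary(fit)) # zero-residual fits warn
    r2 <- sfit$r.squared
    sm <- sfit$coefficients
    slope_p <- if (nrow(sm) >= 2 && !is.nan(sm[2, 4])) sm[2, 4] else NA_real_
  }
  structure(
    list(
      data = tibble::tibble(mean = m, diff = d),
      mean_diff = mean_diff, sd_diff = sd_diff,
      loa_low = mean_diff - 2 * sd_diff, loa_high = mean_diff + 2 * sd_diff,
      slope = slope, intercept = intercept, r2 = r2, slope_p = slope_p,
      n = length(x), degenerate = degenerate
    ),
    class = "vent_bland_altman"
  )
}

#' @export
print.vent_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<Bland-Altman, n = %d: mean diff %.4g (2SD limits %.4g to %.4g)>\n",
    x$n, x$mean_diff, x$loa_low, x$loa_high
  ))
  if (!x$degenerate) {
    cat(sprintf("  diff ~ mean: slope %.4g (p = %.3g), R^2 = %.3f\n",
                x$slope, x$slope_p, x$r2))
  }
  invisible(x)
}

#' @export
tidy.vent_bland_altman <- function(x, ...) {
  tibble::tibble(
    term = c("mean_diff", "sd_diff", "loa_low", "loa_high", "slope",
             "intercept"),
    estimate = c(x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$slope,
                 x$intercept)
  )
}

#' @export
glance.vent_bland_altman <- function(x, ...) {
  tibble::tibble(
    mean_diff = x$mean_diff, sd_diff = x$sd_diff, loa_low = x$loa_low,
    loa_high = x$loa_high, slope = x$slope, slope_p = x$slope_p,
    r_squared = x$r2, n = x$n
  )
}
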