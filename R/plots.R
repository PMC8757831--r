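# ggplot2 views of traces, Bland-Altman analyses and Kv sweeps.

#' Waveform panels of a simulated trace
#'
#' Pressure (system, connector, lung), flow (inhaled/exhaled) and lung
#' volume against time, faceted vertically.
#'
#' @param object a `vent_trace`.
#' @param breaths optional breath numbers to keep.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.vent_trace <- function(object, breaths = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(breaths)) df <- df[df$breath %in% breaths, , drop = FALSE]
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(
      df[, c("time", "p_sys", "p_conn", "p_lung")],
      -"time", names_to = "signal", values_to = "value"
    ) |> dplyr::mutate(panel = "pressure (cmH2O)"),
    tidyr::pivot_longer(
      df[, c("time", "q_i", "q_e")],
      -"time", names_to = "signal", values_to = "value"
    ) |> dplyr::mutate(panel = "flow (l/min)"),
    dplyr::tibble(time = df$time, signal = "v_lung",
                  value = df$v_lung_ml, panel = "lung volume (ml)")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.placement = "outside")
}

#' @rdname autoplot.vent_trace
#' @param trace a `vent_trace`.
#' @export
plot_waveforms <- function(trace, breaths = NULL) {
  autoplot.vent_trace(trace, breaths = breaths)
}

#' Bland-Altman plot
#'
#' Differences against means with the mean-difference line (solid), the
#' two-sided 2 SD limits of agreement (dashed) and the least-squares trend.
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.vent_bland_altman <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of pair", y = "difference (y - x)") +
    ggplot2::theme_minimal()
  if (!object$degenerate) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                                  se = TRUE, colour = "grey40",
                                  linewidth = 0.5)
  }
  p
}

#' Kv design-space sweep plot
#'
#' Metric-vs-Kv curves per ISO case, with the grid values failing the pass
#' criterion shaded.
#'
#' @param object a [kv_sweep()] result.
#' @param metric column to plot, default `"v_t_delivered"` (use
#'   `"peep_achieved"` or `"tex_star"` for Valve D sweeps).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.vent_kv_sweep <- function(object, metric = "v_t_delivered", ...) {
  df <- tibble::as_tibble(object)
  fail_kv <- sort(unique(df$kv[!df$pass]))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$kv, .data[[metric]],
                                        colour = .data$id)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(K[v] ~ (m^3 / h / bar^0.5)), y = metric,
                  colour = "ISO case") +
    ggplot2::theme_minimal()
  if (length(fail_kv)) {
    step <- min(diff(sort(unique(df$kv))), na.rm = TRUE)
    p <- p + ggplot2::annotate("rect",
                               xmin = min(fail_kv) - step / 2,
                               xmax = max(fail_kv) + step / 2,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "red")
  }
  p
}
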