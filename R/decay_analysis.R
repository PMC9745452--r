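# The time-to-90%-decay statistic: the time at which the growth rate dY/dt
# of a fitted (or measured) response has fallen by 90% from its peak.
# Ablation time before this boundary is the "rapidly increasing" phase
# (dominated by resistive heating at the electrode-tissue interface);
# after it, the "slowly increasing" phase (passive conductive heating).

GRID_STEP_DEFAULT <- 0.05   # s
GRID_HORIZON_FACTOR <- 1.5  # x last fitted time
GRID_HORIZON_CAP <- 1e4     # s; hard stop for the adaptive extension

new_decay_result <- function(t_peak, peak_rate, t90, method,
                             crossed = TRUE) {
  structure(list(t_peak = t_peak, peak_rate = peak_rate, t90 = t90,
                 method = method, crossed = crossed),
            class = "decay_result")
}

check_decayable <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  if (isTRUE(fit$degenerate) || !isTRUE(fit$converged))
    stop("refusing to run decay analysis on a degenerate fit: ",
         fit$diagnostic, call. = FALSE)
}

#' Sampled derivative of a fitted growth curve
#'
#' Evaluates dY/dt analytically on a regular grid: `ymax * k * exp(-k t)`
#' for the one-phase model (strictly decreasing from its peak at t = 0),
#' the constant slope for the linear model.
#'
#' @param fit A converged, non-degenerate `growth_fit`.
#' @param grid_step Grid spacing (s), > 0.
#' @param t_max Grid horizon (s); defaults to 1.5 x the last fitted time.
#' @return data.frame with columns `t` and `dydt`.
#' @export
derivative_curve <- function(fit, grid_step = GRID_STEP_DEFAULT,
                             t_max = NULL) {
  check_decayable(fit)
  if (!is.finite(grid_step) || grid_step <= 0)
    stop("grid_step must be positive", call. = FALSE)
  if (is.null(t_max)) t_max <- GRID_HORIZON_FACTOR * fit$t_max
  t <- seq(0, t_max, by = grid_step)
  dydt <- switch(fit$model,
                 one_phase_association = fit$ymax * fit$k * exp(-fit$k * t),
                 linear = rep(fit$slope, length(t)))
  data.frame(t = t, dydt = dydt)
}

#' Time to 90% decay of the peak growth rate
#'
#' For the one-phase association model the growth rate dY/dt peaks at
#' t = 0 with value `ymax * k` and decays exponentially, so the time at
#' which it first reaches 10% of the peak is `ln(10) / k` (independent of
#' the plateau). The `"closed_form"` method returns this exactly; the
#' `"numeric_grid"` method finds the sampled-derivative peak and the first
#' grid time at which dY/dt <= 0.1 x peak (ties count as crossed), and
#' agrees with the closed form within one grid step. The grid horizon
#' starts at 1.5 x the last fitted time and doubles (up to 1e4 s) until
#' the crossing is bracketed, since slow rates place the crossing beyond
#' the observed window.
#'
#' @param fit A converged, non-degenerate one-phase `growth_fit`. Linear
#'   fits have no decaying rate and are refused.
#' @param method `"closed_form"` (default) or `"numeric_grid"`.
#' @param grid_step Grid spacing (s) for the numeric method.
#' @return Object of class `decay_result` with fields `t_peak`,
#'   `peak_rate`, `t90`, `method`.
#' @examples
#' fit <- fit_one_phase(c(10, 20, 30, 40, 50, 60),
#'                      5 * (1 - exp(-0.0622 * c(10, 20, 30, 40, 50, 60))))
#' time_to_90_decay(fit)$t90  # ln(10)/0.0622
#' @export
time_to_90_decay <- function(fit, method = c("closed_form", "numeric_grid"),
                             grid_step = GRID_STEP_DEFAULT) {
  method <- match.arg(method)
  check_decayable(fit)
  if (fit$model != "one_phase_association")
    stop("decay time undefined for non-saturating model '", fit$model, "'",
         call. = FALSE)
  if (method == "closed_form")
    return(new_decay_result(t_peak = 0, peak_rate = fit$ymax * fit$k,
                            t90 = log(10) / fit$k, method = method))

  t_max <- GRID_HORIZON_FACTOR * fit$t_max
  repeat {
    dc <- derivative_curve(fit, grid_step = grid_step, t_max = t_max)
    i_peak <- which.max(dc$dydt)
    peak <- dc$dydt[i_peak]
    after <- seq(i_peak, nrow(dc))
    hit <- after[dc$dydt[after] <= 0.1 * peak]
    if (length(hit))
      return(new_decay_result(t_peak = dc$t[i_peak], peak_rate = peak,
                              t90 = dc$t[hit[1]], method = "numeric_grid"))
    if (t_max >= GRID_HORIZON_CAP)
      return(new_decay_result(t_peak = dc$t[i_peak], peak_rate = peak,
                              t90 = NA_real_, method = "numeric_grid",
                              crossed = FALSE))
    t_max <- min(2 * t_max, GRID_HORIZON_CAP)
  }
}

#' Empirical decay time from a continuous LI trace
#'
#' Estimates the decay statistic directly from sampled LI data: the trace
#' is smoothed by a centered moving average (default window 1 s), the
#' derivative taken by centered finite differences, and the peak and the
#' first subsequent sample at or below 10% of the peak located. Unlike the
#' fitted one-phase curve, a measured trace may peak after t = 0 (catheter
#' settling, noise); `t90` is reported on the trace's own time axis unless
#' `from_peak = TRUE`, which reports it relative to the peak time.
#'
#' @param trace An [li_trace()] spanning at least 5 s with >= 20 samples.
#' @param smoothing_window Moving-average window (s); 0 disables smoothing.
#' @param from_peak Report `t90` as time since the derivative peak.
#' @return `decay_result`; `crossed = FALSE` (with `t90 = NA`) when the
#'   derivative never decays below threshold within the trace.
#' @export
time_to_90_decay_empirical <- function(trace, smoothing_window = 1,
                                       from_peak = FALSE) {
  stopifnot(inherits(trace, "li_trace"))
  tt <- trace$times; y <- trace$li_values
  if (length(tt) < 20L || (max(tt) - min(tt)) < 5)
    stop("trace too short: need >= 20 samples spanning >= 5 s",
         call. = FALSE)

  dt <- stats::median(diff(tt))
  if (smoothing_window > 0) {
    half <- max(0L, floor(smoothing_window / (2 * dt)))
    if (half > 0) {
      w <- 2L * half + 1L
      ys <- stats::filter(y, rep(1 / w, w), sides = 2)
      # near the edges shrink the window symmetrically so every smoothed
      # sample stays centred on its own time (an asymmetric edge window
      # would shift the derivative peak by half a window)
      for (i in which(is.na(ys))) {
        h <- min(i - 1L, length(y) - i, half)
        ys[i] <- mean(y[(i - h):(i + h)])
      }
      y <- as.numeric(ys)
    }
  }

  n <- length(y)
  dydt <- numeric(n)
  dydt[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  dydt[1] <- (y[2] - y[1]) / (tt[2] - tt[1])
  dydt[n] <- (y[n] - y[n - 1]) / (tt[n] - tt[n - 1])

  i_peak <- which.max(dydt)
  peak <- dydt[i_peak]
  if (peak <= 0)
    stop("no rise detected: derivative peak is not positive", call. = FALSE)

  after <- seq(i_peak, n)
  hit <- after[dydt[after] <= 0.1 * peak]
  if (!length(hit))
    return(new_decay_result(t_peak = tt[i_peak], peak_rate = peak,
                            t90 = NA_real_, method = "numeric_grid",
                            crossed = FALSE))
  t90 <- tt[hit[1]] - if (from_peak) tt[i_peak] else 0
  new_decay_result(t_peak = tt[i_peak], peak_rate = peak, t90 = t90,
                   method = "numeric_grid")
}

#' Partition ablation times into rapidly/slowly increasing phases
#'
#' Labels each queried time relative to the decay boundary `t90` of a fit:
#' strictly before the boundary is `"rapidly_increasing"`, at or after it
#' `"slowly_increasing"` (the boundary itself belongs to the slow phase).
#'
#' @param fit A converged, non-degenerate one-phase `growth_fit`.
#' @param times Times to label (s).
#' @param ... Passed to [time_to_90_decay()].
#' @return List with `boundary` (s) and `labels` (character vector).
#' @export
phase_partition <- function(fit, times, ...) {
  dr <- time_to_90_decay(fit, ...)
  labels <- ifelse(times < dr$t90, "rapidly_increasing", "slowly_increasing")
  structure(list(boundary = dr$t90, times = as.numeric(times),
                 labels = labels),
            class = "phase_partition")
}

#' @export
print.decay_result <- function(x, ...) {
  if (isTRUE(x$crossed))
    cat(sprintf("<decay_result> t90 = %.2f s (peak dY/dt = %.4g at t = %.2f s, %s)\n",
                x$t90, x$peak_rate, x$t_peak, x$method))
  else
    cat(sprintf("<decay_result> crossing absent (peak dY/dt = %.4g at t = %.2f s)\n",
                x$peak_rate, x$t_peak))
  invisible(x)
}
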