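# Independent reference implementations: exact first-order filter responses
# on piecewise-constant inputs, the closed-form single-spike LTP integral,
# and a fine-grid scalar-loop integrator.  These exist to validate the
# vectorized Euler path before any fitted result is trusted.

#' Piecewise-constant voltage input
#'
#' @param times segment edges (ms), strictly increasing; `length(levels) + 1`
#'   values.  The input equals `levels[k]` on `[times[k], times[k+1])`.
#' @param levels voltage level per segment (mV).
#' @param spike_times optional presynaptic spike times within the span.
#' @return An object of class `"piecewise_input"`.
#' @export
piecewise_input <- function(times, levels, spike_times = numeric()) {
  times <- as.numeric(times); levels <- as.numeric(levels)
  if (length(times) != length(levels) + 1L)
    stop("need exactly one level per segment (length(times) == length(levels) + 1)")
  if (any(diff(times) <= 0)) stop("segment edges must be strictly increasing")
  if (length(spike_times) &&
      (min(spike_times) < times[1L] || max(spike_times) > times[length(times)]))
    stop("spike times must lie within the input span")
  structure(list(times = times, levels = levels,
                 spike_times = as.numeric(spike_times)),
            class = "piecewise_input")
}

#' Exact first-order low-pass response to a piecewise-constant input
#'
#' Solves `tau dy/dt = -y + u(t)` exactly, segment by segment: within a
#' segment of level `L` entered at `t_s` with value `v`, the response is
#' `L + (v - L) exp(-(t - t_s)/tau)`.
#'
#' @param input a [piecewise_input()].
#' @param tau filter time constant (ms).
#' @param t_query query time(s) (ms), within the input span.
#' @param v0 filter value at the start of the input (default 0 = rest).
#' @return Filter output (mV) at each query time.
#' @export
analytic_filter <- function(input, tau, t_query, v0 = 0) {
  stopifnot(inherits(input, "piecewise_input"), tau > 0)
  tq <- as.numeric(t_query)
  if (any(tq < input$times[1L] - 1e-9) ||
      any(tq > input$times[length(input$times)] + 1e-9))
    stop("t_query outside the input span")
  out <- numeric(length(tq))
  for (j in seq_along(tq)) {
    v <- v0
    t <- tq[j]
    for (k in seq_along(input$levels)) {
      a <- input$times[k]; b <- input$times[k + 1L]
      end <- min(b, t)
      if (end <= a) break
      L <- input$levels[k]
      v <- L + (v - L) * exp(-(end - a) / tau)
      if (t <= b) break
    }
    out[j] <- v
  }
  out
}

#' Exact glutamate trace at query times
#'
#' Closed form of the spike-triggered trace: a sum of unit jumps decaying
#' with `tau_x`, `x_bar(t) = sum_{s <= t} exp(-(t - s)/tau_x)`.
#'
#' @param spike_times presynaptic spike times (ms).
#' @param tau_x trace decay time constant (ms).
#' @param t_query query time(s) (ms).
#' @return Trace value at each query time.
#' @export
analytic_xbar <- function(spike_times, tau_x, t_query) {
  vapply(as.numeric(t_query), function(t) {
    s <- spike_times[spike_times <= t + 1e-12]
    sum(exp(-(t - s) / tau_x))
  }, numeric(1))
}

#' Closed-form LTP from a single spike under equilibrated clamp
#'
#' With the voltage clamped at `u0`, both filters equilibrated at `u0`, the
#' veto disabled (`b_theta = 0`) and a single presynaptic spike, the total
#' accumulated potentiation is the exact time integral of the LTP rate:
#' `A_LTP * max(u0 - theta_plus, 0) * tau_x` (the trace integrates to
#' `tau_x` per unit jump).
#'
#' @param u0 clamp level (mV relative to rest).
#' @param params a [plasticity_params()] object (only `A_LTP`, `theta_plus`
#'   and `tau_x` are used).
#' @return Accumulated potentiation `delta w_ltp` (dimensionless).
#' @export
analytic_single_spike_ltp <- function(u0, params) {
  params[["A_LTP"]] * max(u0 - params[["theta_plus"]], 0) * params[["tau_x"]]
}

#' Fine-grid reference integration
#'
#' Re-integrates a protocol with an independently written scalar Euler loop
#' at a refined step `dt_fine`, linearly interpolating the voltage trace
#' between its samples.  Serves as a convergence reference for
#' [vbp_simulate()]; it shares the model equations but none of the
#' vectorized implementation.
#'
#' @inheritParams vbp_simulate
#' @param dt_fine refined step size (ms); must be below the trace `dt`.
#' @return A `"vbp_sim"` object.
#' @export
fine_grid_reference <- function(trace, spikes, params, dt_fine = 1e-3,
                                w_init = 0.5) {
  trace <- as_voltage_trace(trace)
  spikes <- as_spike_train(spikes)
  validate_params(params)
  if (dt_fine >= trace$dt)
    stop("dt_fine must be smaller than the trace dt")
  dur <- trace_duration(trace)
  n <- ceiling(dur / dt_fine - 1e-9)
  dt <- dur / n  # exact cover of the span
  t_coarse <- trace$t0 + (seq_along(trace$values) - 1L) * trace$dt
  u <- stats::approx(t_coarse, trace$values,
                     xout = trace$t0 + seq_len(n) * dt, rule = 2)$y
  s <- bin_spikes(spikes$times, trace$t0, dt, n)
  p <- params
  ax <- 1 - dt / p[["tau_x"]]
  kp <- dt / p[["tau_plus"]]; km <- dt / p[["tau_minus"]]
  kt <- dt / p[["tau_theta"]]
  ALTP <- p[["A_LTP"]]; ALTD <- p[["A_LTD"]]
  thp <- p[["theta_plus"]]; th0 <- p[["theta_0"]]; bth <- p[["b_theta"]]
  x <- 0; up <- 0; um <- 0; th <- 0; wp <- 0; wd <- 0
  for (i in seq_len(n)) {
    x <- x * ax + s[i]
    ui <- u[i]
    up <- up + kp * (ui - up)
    um <- um + km * (ui - um)
    rp <- ALTP * x * max(up - thp, 0)
    rm <- ALTD * x * max(um - th0 - th, 0)
    wp <- wp + rp * dt
    wd <- wd + rm * dt
    th <- th * (1 - kt) + bth * kt * rp
  }
  w_final <- w_init + wp - wd
  structure(list(w_initial = w_init, w_final = w_final,
                 relative_change = (w_final - w_init) / w_init,
                 w_ltp = wp, w_ltd = wd, trajectory = NULL),
            class = "vbp_sim")
}
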