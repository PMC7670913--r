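# Forward-Euler integration of the plasticity rule.
#
# One step of size dt applies, in this fixed order:
#   1. x_bar decays by (1 - dt/tau_x), then gains +1 per spike in (t, t+dt];
#   2. u_bar_plus / u_bar_minus relax toward the step's voltage sample;
#   3. LTP rate  r+ = A_LTP * x_bar * [u_bar_plus  - theta_plus]_+  and
#      LTD rate  r- = A_LTD * x_bar * [u_bar_minus - (theta_0 + theta)]_+
#      are evaluated with the just-updated traces (theta from the previous
#      step, so the veto acts with a one-step lag);
#   4. w_ltp += r+ * dt, w_ltd += r- * dt;
#   5. theta decays by (1 - dt/tau_theta) and gains b_theta * r+ * dt/tau_theta
#      (explicit Euler of tau_theta dtheta/dt = -theta + b_theta dw_ltp/dt).
# The weight w = w_init + w_ltp - w_ltd is a pure read-out; it is never fed
# back into the dynamics.

#' Fresh model state
#'
#' All filters and the variable part of the LTD threshold start at 0 (= rest)
#' at the beginning of a protocol.
#'
#' @param w_init initial synaptic weight (dimensionless).
#' @return A named list with components `x_bar`, `u_bar_plus`, `u_bar_minus`,
#'   `theta_var`, `w_ltp`, `w_ltd`, `w`.
#' @export
new_model_state <- function(w_init = 0.5) {
  list(x_bar = 0, u_bar_plus = 0, u_bar_minus = 0, theta_var = 0,
       w_ltp = 0, w_ltd = 0, w = w_init)
}

#' Advance the plasticity rule by one Euler step
#'
#' Exposes the elementary update of the rule; [vbp_simulate()] applies the
#' same update over a whole trace (and is much faster).  Useful for
#' inspecting the update order and for cross-checking the vectorized path.
#'
#' @param state model state as returned by [new_model_state()] or a previous
#'   call.
#' @param u_t voltage sample driving this step (mV relative to rest).
#' @param n_spikes number of presynaptic spikes arriving within this step.
#' @param dt step size (ms); must be positive and smaller than every time
#'   constant.
#' @param params a [plasticity_params()] object.
#' @return The updated state list.
#' @export
plasticity_step <- function(state, u_t, n_spikes, dt, params) {
  if (!is.finite(u_t))
    stop("non-finite voltage sample u_t = ", u_t)
  if (!is.finite(dt) || dt <= 0)
    stop("dt must be positive, got ", dt)
  p <- params
  x  <- state$x_bar * (1 - dt / p[["tau_x"]]) + n_spikes
  kp <- dt / p[["tau_plus"]]; km <- dt / p[["tau_minus"]]
  up <- state$u_bar_plus  * (1 - kp) + kp * u_t
  um <- state$u_bar_minus * (1 - km) + km * u_t
  rp <- p[["A_LTP"]] * x * max(up - p[["theta_plus"]], 0)
  rm <- p[["A_LTD"]] * x * max(um - (p[["theta_0"]] + state$theta_var), 0)
  w_ltp <- state$w_ltp + rp * dt
  w_ltd <- state$w_ltd + rm * dt
  kt <- dt / p[["tau_theta"]]
  th <- state$theta_var * (1 - kt) + p[["b_theta"]] * kt * rp
  list(x_bar = x, u_bar_plus = up, u_bar_minus = um, theta_var = th,
       w_ltp = w_ltp, w_ltd = w_ltd,
       w = state$w - state$w_ltp + state$w_ltd + w_ltp - w_ltd)
}

# Compiled core (src/sim_core.cpp): identical arithmetic to plasticity_step.
# `values` are the voltage samples at the END of each step (the first sample
# of a trace sets t0 only), `spike_counts` the per-step spike counts.
.sim_core <- function(values, dt, spike_counts, p, w_init = 0.5,
                      clip_zero = FALSE, trajectory = FALSE, t0 = 0) {
  n <- length(values)
  cc <- .sim_core_cpp(values, as.numeric(spike_counts), dt,
                      as.numeric(p[.PAR_NAMES]), w_init, clip_zero,
                      trajectory)
  res <- list(
    w_initial = w_init,
    w_final = cc$w_final,
    relative_change = (cc$w_final - w_init) / w_init,
    w_ltp = cc$w_ltp,
    w_ltd = cc$w_ltd,
    trajectory = NULL)
  if (trajectory) {
    tj <- cc$traj
    w <- w_init + tj$w_ltp - tj$w_ltd
    if (clip_zero) w <- pmax(w, 0)
    res$trajectory <- data.frame(
      time = t0 + seq_len(n) * dt, u = values, x_bar = tj$x_bar,
      u_bar_plus = tj$u_bar_plus, u_bar_minus = tj$u_bar_minus,
      theta_var = tj$theta_var, w_ltp = tj$w_ltp, w_ltd = tj$w_ltd, w = w)
  }
  class(res) <- "vbp_sim"
  res
}

#' Simulate a full plasticity protocol
#'
#' Integrates the plasticity rule over a voltage trace with a companion
#' presynaptic spike train, starting from a fresh state (all filters at rest,
#' weight at `w_init`), and returns the final weight and the relative weight
#' change `(w_f - w_i)/w_i`.
#'
#' @param trace a [voltage_trace()] (mV relative to rest).
#' @param spikes a [spike_train()] or numeric vector of spike times (ms); all
#'   spikes must fall within the trace span.
#' @param params a [plasticity_params()] object.
#' @param w_init initial synaptic weight; the conventional value is 0.5.
#' @param record_trajectory if `TRUE`, attach a per-step `data.frame` of all
#'   state variables.
#' @param clip_zero if `TRUE`, floor the read-out weight at zero (off by
#'   default; the rule itself imposes no hard bounds during induction).
#' @return An object of class `"vbp_sim"`: a list with `w_initial`,
#'   `w_final`, `relative_change`, the accumulated `w_ltp` and `w_ltd`, and
#'   optionally `trajectory`.
#' @export
#' @examples
#' tr <- make_clamp_trace(20, duration = 300, dt = 0.1)
#' vbp_simulate(tr, spike_train(50), vbp_preset_params("clamp-linear"))
vbp_simulate <- function(trace, spikes, params, w_init = 0.5,
                         record_trajectory = FALSE, clip_zero = FALSE) {
  trace <- as_voltage_trace(trace)
  spikes <- as_spike_train(spikes)
  validate_params(params)
  n_steps <- length(trace$values) - 1L
  counts <- bin_spikes(spikes$times, trace$t0, trace$dt, n_steps)
  .sim_core(trace$values[-1L], trace$dt, counts, params, w_init = w_init,
            clip_zero = clip_zero, trajectory = record_trajectory,
            t0 = trace$t0)
}

#' @export
print.vbp_sim <- function(x, ...) {
  cat(sprintf(
    "Plasticity simulation: w %g -> %g (%+.4g%% of initial)\n  w_ltp = %.4g, w_ltd = %.4g\n",
    x$w_initial, x$w_final, 100 * x$relative_change, x$w_ltp, x$w_ltd))
  invisible(x)
}

#' Simulate a protocol whose trials split into several trace types
#'
#' Some induction protocols evoke different dendritic responses from trial to
#' trial (e.g. 60 pairings of which roughly a third produce a supralinear
#' dendritic spike and the rest a linear EPSP summation).  When repetitions
#' are far enough apart for the state to relax back to rest between trials,
#' the total weight change is the repetition-weighted sum of independent
#' single-trial changes, each computed from a fresh state.
#'
#' @param components a list of components, each a list with elements `trace`
#'   (a [voltage_trace()]), `spikes` (a [spike_train()] or numeric vector)
#'   and `reps` (a non-negative integer repetition count).  All traces must
#'   share the same `dt`.
#' @inheritParams vbp_simulate
#' @return A `"vbp_sim"` object; `w_final` is `w_init` plus the summed
#'   weighted per-trial changes.
#' @export
simulate_trial_mixture <- function(components, params, w_init = 0.5) {
  if (!length(components)) stop("need at least one component")
  dts <- vapply(components, function(cc) as_voltage_trace(cc$trace)$dt,
                numeric(1))
  if (max(dts) - min(dts) > 1e-12)
    stop("all components must share the same dt (got ",
         paste(unique(dts), collapse = ", "), ")")
  reps <- vapply(components, function(cc) {
    r <- cc$reps
    if (is.null(r)) r <- 1
    if (!is.finite(r) || r < 0 || r != round(r))
      stop("repetitions must be non-negative integers")
    as.numeric(r)
  }, numeric(1))
  ltp <- 0; ltd <- 0
  for (i in seq_along(components)) {
    if (reps[i] == 0) next
    s <- vbp_simulate(components[[i]]$trace, components[[i]]$spikes,
                      params, w_init = w_init)
    ltp <- ltp + reps[i] * s$w_ltp
    ltd <- ltd + reps[i] * s$w_ltd
  }
  w_final <- w_init + ltp - ltd
  structure(list(w_initial = w_init, w_final = w_final,
                 relative_change = (w_final - w_init) / w_init,
                 w_ltp = ltp, w_ltd = ltd, trajectory = NULL),
            class = "vbp_sim")
}
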