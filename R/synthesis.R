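# Synthetic dendritic voltage traces and protocol batteries.
#
# The trace generator emulates the protocol classes used in plasticity
# experiments with idealized voltage kernels: double-exponential EPSPs,
# triangular backpropagating action potentials (bAPs) with an exponential
# after-depolarization, a rounded-rectangular dendritic-spike waveform,
# constant voltage clamp, and square pulses.  Real dendritic recordings are
# of course richer; the surrogates are only required to exercise every
# pathway of the plasticity rule.

#' Voltage kernel shapes for synthetic traces
#'
#' @param epsp_amp EPSP peak amplitude (mV).
#' @param epsp_tau_rise,epsp_tau_decay rise and decay time constants of the
#'   double-exponential EPSP kernel (ms); rise must be below decay.
#' @param bap_amp bAP peak amplitude at the dendritic location (mV).
#' @param bap_width bAP duration (ms); the spike decays linearly from its
#'   peak to the after-depolarization level over this window.
#' @param adp_frac after-depolarization amplitude as a fraction of `bap_amp`.
#' @param adp_tau after-depolarization decay time constant (ms); long values
#'   let depolarization persist between high-frequency pairings.
#' @param dspike_amp dendritic (NMDA/calcium) spike plateau amplitude (mV).
#' @param dspike_duration dendritic spike plateau duration (ms).
#' @return A named list of class `"kernel_params"`.
#' @export
kernel_params <- function(epsp_amp = 8, epsp_tau_rise = 0.5,
                          epsp_tau_decay = 10,
                          bap_amp = 45, bap_width = 2,
                          adp_frac = 0.2, adp_tau = 20,
                          dspike_amp = 35, dspike_duration = 30) {
  k <- list(epsp_amp = epsp_amp, epsp_tau_rise = epsp_tau_rise,
            epsp_tau_decay = epsp_tau_decay, bap_amp = bap_amp,
            bap_width = bap_width, adp_frac = adp_frac, adp_tau = adp_tau,
            dspike_amp = dspike_amp, dspike_duration = dspike_duration)
  num <- unlist(k)
  if (!all(is.finite(num)) || any(num < 0))
    stop("kernel parameters must be finite and non-negative")
  if (epsp_tau_rise >= epsp_tau_decay)
    stop("epsp_tau_rise must be below epsp_tau_decay")
  if (adp_frac > 1) stop("adp_frac must be in [0, 1]")
  structure(k, class = "kernel_params")
}

# waveform evaluators: s = time since event onset (vector, may be < 0)
.epsp_wave <- function(s, k) {
  tr <- k$epsp_tau_rise; td <- k$epsp_tau_decay
  s_peak <- tr * td / (td - tr) * log(td / tr)
  norm <- exp(-s_peak / td) - exp(-s_peak / tr)
  out <- numeric(length(s))
  i <- s >= 0
  out[i] <- k$epsp_amp * (exp(-s[i] / td) - exp(-s[i] / tr)) / norm
  out
}

.bap_wave <- function(s, k) {
  out <- numeric(length(s))
  a0 <- k$adp_frac * k$bap_amp
  i <- s >= 0 & s < k$bap_width
  out[i] <- k$bap_amp - (k$bap_amp - a0) * s[i] / k$bap_width
  j <- s >= k$bap_width
  out[j] <- a0 * exp(-(s[j] - k$bap_width) / k$adp_tau)
  out
}

.dspike_wave <- function(s, k, tau_rise = 1, tau_fall = 3) {
  out <- numeric(length(s))
  i <- s >= 0 & s < k$dspike_duration
  out[i] <- k$dspike_amp * (1 - exp(-s[i] / tau_rise))
  j <- s >= k$dspike_duration
  edge <- k$dspike_amp * (1 - exp(-k$dspike_duration / tau_rise))
  out[j] <- edge * exp(-(s[j] - k$dspike_duration) / tau_fall)
  out
}

#' Constant voltage-clamp trace
#'
#' @param u0 clamp level (mV relative to rest).
#' @param duration trace duration (ms).
#' @param dt sample interval (ms).
#' @param t0 start time (ms).
#' @return A [voltage_trace()] holding `u0` throughout.
#' @export
make_clamp_trace <- function(u0, duration, dt = 0.1, t0 = 0) {
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  n <- floor(duration / dt + 1e-9) + 1L
  voltage_trace(rep(as.numeric(u0), n), dt = dt, t0 = t0)
}

#' Voltage-clamp pairing protocol
#'
#' Constant clamp at `u0` paired with a train of brief presynaptic
#' stimulations: `n_pulses` afferent stimulations at `frequency_hz`.  The
#' clamp starts `lead` ms before the first stimulation (letting the voltage
#' filters equilibrate) and extends `tail` ms past the last one.
#'
#' @param u0 clamp level (mV relative to rest).
#' @param n_pulses number of presynaptic stimulations.
#' @param frequency_hz stimulation frequency (Hz).
#' @param dt sample interval (ms).
#' @param lead,tail clamp time before the first and after the last
#'   stimulation (ms).
#' @return A list with elements `trace` and `spikes`.
#' @export
make_clamp_protocol <- function(u0, n_pulses = 100, frequency_hz = 2,
                                dt = 0.1, lead = 300, tail = 300) {
  stopifnot(n_pulses >= 1, frequency_hz > 0)
  period <- 1000 / frequency_hz
  times <- lead + (seq_len(n_pulses) - 1L) * period
  dur <- times[n_pulses] + tail
  list(trace = make_clamp_trace(u0, dur, dt = dt),
       spikes = spike_train(times))
}

#' Square-pulse protocol
#'
#' The dendritic voltage is held at rest except for one square pulse of
#' height `delta_u` and duration `T`, paired with a single presynaptic spike
#' at `spike_offset` ms relative to the pulse onset (negative = before the
#' pulse; `T + 10` places it 10 ms after the pulse end; `T/2` centers it).
#'
#' @param delta_u pulse amplitude (mV).
#' @param T pulse duration (ms).
#' @param spike_offset spike time relative to pulse onset (ms).
#' @param dt sample interval (ms).
#' @param lead,tail rest time before the pulse/first event and after the
#'   last event (ms).
#' @return A list with elements `trace` and `spikes`.
#' @export
make_square_pulse_protocol <- function(delta_u, T, spike_offset, dt = 0.1,
                                       lead = 50, tail = 300) {
  stopifnot(is.finite(T), T > 0)
  t_on <- lead + max(0, -spike_offset)
  spike_t <- t_on + spike_offset
  if (spike_t < 0) stop("spike offset places the spike before the trace start")
  dur <- max(t_on + T, spike_t) + tail
  n <- floor(dur / dt + 1e-9) + 1L
  t <- (seq_len(n) - 1L) * dt
  v <- ifelse(t >= t_on & t < t_on + T, as.numeric(delta_u), 0)
  list(trace = voltage_trace(v, dt = dt), spikes = spike_train(spike_t))
}

#' Plasticity protocol specification
#'
#' Describes one induction protocol of the battery.  Three types are
#' supported: `"clamp"` (constant voltage paired with a presynaptic pulse
#' train), `"pulse"` (a single square voltage pulse paired with one spike,
#' repeated as independent trials) and `"pairing"` (presynaptic EPSPs paired
#' with postsynaptic bAP bursts, optionally with dendritic spikes in a
#' fraction of the trials).
#'
#' @param type protocol type, see above.
#' @param id protocol identifier (defaults to a descriptive string).
#' @param repetitions number of pairings/trials (>= 1).
#' @param frequency_hz repetition frequency of the pairings (Hz).
#' @param interval_ms pre-to-post interval (ms, pairing type): positive means
#'   the presynaptic spike precedes the (first) postsynaptic event.
#' @param n_post number of postsynaptic spikes per pairing (0 allowed).
#' @param post_freq_hz intra-burst frequency of postsynaptic spikes (Hz).
#' @param composition named fractions over trial kinds `"linear"` and
#'   `"supra"`; must sum to 1.  `"supra"` trials add a dendritic-spike
#'   waveform at the postsynaptic event.
#' @param clamp_mv clamp level (mV, clamp type).
#' @param pulse a list `list(delta_u =, T =, spike_offset =)` (pulse type).
#' @param per_trial logical; if `TRUE` the repetitions are simulated as
#'   independent single trials from a fresh state (exact when the
#'   inter-pairing interval is long against all time constants), otherwise
#'   one continuous trace carries all repetitions.  Default: per-trial below
#'   0.5 Hz, continuous at and above.
#' @return An object of class `"protocol_spec"`.
#' @export
protocol_spec <- function(type = c("pairing", "clamp", "pulse"), id = NULL,
                          repetitions = 1, frequency_hz = 1,
                          interval_ms = 10, n_post = 1, post_freq_hz = 200,
                          composition = c(linear = 1),
                          clamp_mv = NULL, pulse = NULL, per_trial = NULL) {
  type <- match.arg(type)
  stopifnot(repetitions >= 1, repetitions == round(repetitions),
            frequency_hz > 0)
  if (abs(sum(composition) - 1) > 1e-9 || any(composition < 0))
    stop("composition fractions must be non-negative and sum to 1")
  if (!all(names(composition) %in% c("linear", "supra")))
    stop("composition names must be 'linear' and/or 'supra'")
  if (type == "clamp" && is.null(clamp_mv))
    stop("clamp protocols need clamp_mv")
  if (type == "pulse") {
    if (is.null(pulse) || !all(c("delta_u", "T", "spike_offset") %in% names(pulse)))
      stop("pulse protocols need pulse = list(delta_u, T, spike_offset)")
  }
  if (is.null(per_trial)) per_trial <- frequency_hz < 0.5
  if (is.null(id)) {
    id <- switch(type,
      clamp = sprintf("clamp_%gmV_%gHz_x%d", clamp_mv, frequency_hz,
                      repetitions),
      pulse = sprintf("pulse_%gmV_T%g_off%g_x%d", pulse$delta_u, pulse$T,
                      pulse$spike_offset, repetitions),
      pairing = sprintf("pair_%+gms_%gHz_x%d_%dpost", interval_ms,
                        frequency_hz, repetitions, n_post))
  }
  structure(list(type = type, id = id, repetitions = repetitions,
                 frequency_hz = frequency_hz, interval_ms = interval_ms,
                 n_post = n_post, post_freq_hz = post_freq_hz,
                 composition = composition, clamp_mv = clamp_mv,
                 pulse = pulse, per_trial = per_trial),
            class = "protocol_spec")
}

# event times (relative to the presynaptic spike at 0) for one pairing
.pairing_events <- function(spec) {
  post <- numeric(0)
  if (spec$n_post > 0)
    post <- spec$interval_ms +
      (seq_len(spec$n_post) - 1L) * 1000 / spec$post_freq_hz
  list(pre = 0, post = post)
}

#' Build a pairing protocol as one or more trace/spike components
#'
#' Constructs, for each trial kind of `spec$composition`, a voltage trace by
#' linear superposition of EPSP kernels (at presynaptic spike times), bAP
#' waveforms with after-depolarization (at postsynaptic spike times) and --
#' for `"supra"` trials -- a dendritic-spike waveform at the first
#' postsynaptic event (or at the presynaptic time when `n_post = 0`).
#' Repetitions are either laid out on one continuous trace at
#' `spec$frequency_hz` (so that residual depolarization can accumulate
#' between pairings) or returned as a single-pairing trace with a repetition
#' count (`spec$per_trial`).
#'
#' @param spec a [protocol_spec()] of type `"pairing"`.
#' @param kernels a [kernel_params()] object.
#' @param dt sample interval (ms).
#' @return A list of components `list(trace =, spikes =, reps =)`, one per
#'   trial kind, suitable for [simulate_trial_mixture()].
#' @export
make_pairing_protocol <- function(spec, kernels = kernel_params(), dt = 0.1) {
  stopifnot(inherits(spec, "protocol_spec"), spec$type == "pairing")
  ev <- .pairing_events(spec)
  ev_all <- c(ev$pre, ev$post)
  span <- diff(range(ev_all))
  period <- 1000 / spec$frequency_hz
  if (!spec$per_trial && period < span)
    stop("inter-pairing period (", period,
         " ms) is shorter than the pairing pattern span (", span, " ms)")
  tail_tau <- max(kernels$epsp_tau_decay, kernels$adp_tau, 10)
  lead <- 50
  reps_per_kind <- .split_reps(spec$composition, spec$repetitions)
  kinds <- names(reps_per_kind)[reps_per_kind > 0]
  lapply(stats::setNames(kinds, kinds), function(kind) {
    n_rep <- if (spec$per_trial) 1L else reps_per_kind[[kind]]
    base <- lead - min(ev_all) + (seq_len(n_rep) - 1L) * period
    pre_t <- base + ev$pre
    post_t <- as.numeric(outer(ev$post, base, "+"))
    dur <- max(c(pre_t, post_t)) + 5 * tail_tau + 50
    n <- floor(dur / dt + 1e-9) + 1L
    t <- (seq_len(n) - 1L) * dt
    v <- numeric(n)
    for (e in pre_t)  v <- v + .epsp_wave(t - e, kernels)
    for (e in post_t) v <- v + .bap_wave(t - e, kernels)
    if (kind == "supra") {
      ds_t <- if (length(post_t)) base + min(ev$post) else pre_t
      for (e in ds_t) v <- v + .dspike_wave(t - e, kernels)
    }
    list(trace = voltage_trace(v, dt = dt),
         spikes = spike_train(sort(pre_t)),
         reps = if (spec$per_trial) reps_per_kind[[kind]] else 1L)
  }) |> unname()
}

.split_reps <- function(composition, repetitions) {
  r <- floor(composition * repetitions)
  left <- repetitions - sum(r)
  if (left > 0) {  # give remainders to the largest fractional parts
    frac <- composition * repetitions - r
    ord <- order(frac, decreasing = TRUE)
    r[ord[seq_len(left)]] <- r[ord[seq_len(left)]] + 1
  }
  as.list(r)
}

#' Realize a protocol specification as simulation components
#'
#' @param spec a [protocol_spec()].
#' @param kernels a [kernel_params()] object (pairing protocols).
#' @param dt sample interval (ms).
#' @return A list of components `list(trace =, spikes =, reps =)`.
#' @export
make_protocol <- function(spec, kernels = kernel_params(), dt = 0.1) {
  stopifnot(inherits(spec, "protocol_spec"))
  switch(spec$type,
    clamp = {
      pr <- make_clamp_protocol(spec$clamp_mv, n_pulses = spec$repetitions,
                                frequency_hz = spec$frequency_hz, dt = dt,
                                lead = 150, tail = 200)
      list(list(trace = pr$trace, spikes = pr$spikes, reps = 1L))
    },
    pulse = {
      pr <- make_square_pulse_protocol(spec$pulse$delta_u, spec$pulse$T,
                                       spec$pulse$spike_offset, dt = dt)
      list(list(trace = pr$trace, spikes = pr$spikes,
                reps = spec$repetitions))
    },
    pairing = make_pairing_protocol(spec, kernels = kernels, dt = dt))
}

#' One labelled plasticity outcome
#'
#' @param id unique protocol identifier.
#' @param components list of `list(trace =, spikes =, reps =)` components.
#' @param dw_exp experimental (or synthetic) relative weight change, as a
#'   fraction of the initial weight (e.g. `+0.22` for 122% of initial).
#' @return An object of class `"protocol_record"`.
#' @export
protocol_record <- function(id, components, dw_exp) {
  stopifnot(is.character(id), length(id) == 1L, is.list(components),
            length(components) >= 1L, is.finite(dw_exp))
  structure(list(id = id, components = components, dw_exp = dw_exp),
            class = "protocol_record")
}

#' Collection of plasticity outcomes
#'
#' @param records list of [protocol_record()]s with unique ids.
#' @return An object of class `"vbp_dataset"`.
#' @export
vbp_dataset <- function(records) {
  stopifnot(is.list(records), length(records) >= 1L)
  ok <- vapply(records, inherits, logical(1), "protocol_record")
  if (!all(ok)) stop("all elements must be protocol_record objects")
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("protocol ids must be unique")
  structure(records, class = "vbp_dataset")
}

#' @export
print.vbp_dataset <- function(x, ...) {
  cat("Plasticity dataset:", length(x), "protocol outcomes\n")
  df <- data.frame(id = vapply(x, `[[`, character(1), "id"),
                   components = vapply(x, function(r) length(r$components),
                                       integer(1)),
                   dw_exp = vapply(x, `[[`, numeric(1), "dw_exp"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
`[.vbp_dataset` <- function(x, i) {
  vbp_dataset(unclass(x)[i])
}

#' Predicted relative weight change for records
#'
#' @param params a [plasticity_params()] object.
#' @param data a [vbp_dataset()] or single [protocol_record()].
#' @param w_init initial weight.
#' @return Numeric vector of predicted relative weight changes (fractions).
#' @export
predict_dw <- function(params, data, w_init = 0.5) {
  if (inherits(data, "protocol_record")) data <- vbp_dataset(list(data))
  vapply(data, function(r)
    simulate_trial_mixture(r$components, params,
                           w_init = w_init)$relative_change,
    numeric(1))
}

#' Default synthetic protocol battery
#'
#' Fifteen diverse protocols spanning voltage clamp at several levels,
#' square pulses at three spike placements, spike-timing pairings at several
#' intervals and repetition frequencies, a burst pairing, and a
#' linear/supralinear trial mixture.  The battery is designed to constrain
#' all nine rule parameters and is the default input of the parameter
#' recovery and validation studies.
#'
#' @return A list of [protocol_spec()]s.
#' @export
default_protocol_battery <- function() {
  list(
    protocol_spec("clamp", clamp_mv = 7,  repetitions = 8, frequency_hz = 10),
    protocol_spec("clamp", clamp_mv = 10, repetitions = 8, frequency_hz = 10),
    protocol_spec("clamp", clamp_mv = 13, repetitions = 8, frequency_hz = 10),
    protocol_spec("clamp", clamp_mv = 16, repetitions = 8, frequency_hz = 10),
    protocol_spec("clamp", clamp_mv = 22, repetitions = 8, frequency_hz = 10),
    protocol_spec("pulse", pulse = list(delta_u = 18, T = 10, spike_offset = 5),
                  repetitions = 60),
    protocol_spec("pulse", pulse = list(delta_u = 14, T = 30, spike_offset = 40),
                  repetitions = 60),
    protocol_spec("pulse", pulse = list(delta_u = 20, T = 30, spike_offset = 45),
                  repetitions = 60),
    protocol_spec("pulse", pulse = list(delta_u = 25, T = 15, spike_offset = -5),
                  repetitions = 60),
    protocol_spec("pulse", pulse = list(delta_u = 25, T = 15, spike_offset = -15),
                  repetitions = 60),
    protocol_spec("pairing", interval_ms = 10,  repetitions = 30,
                  frequency_hz = 20),
    protocol_spec("pairing", interval_ms = -10, repetitions = 30,
                  frequency_hz = 20),
    protocol_spec("pairing", interval_ms = 10,  repetitions = 8,
                  frequency_hz = 40),
    protocol_spec("pairing", interval_ms = 10,  repetitions = 10,
                  frequency_hz = 10, n_post = 3, post_freq_hz = 200),
    protocol_spec("pairing", interval_ms = 10,  repetitions = 60,
                  frequency_hz = 0.1,
                  composition = c(linear = 2 / 3, supra = 1 / 3),
                  id = "pair_mixture_0.1Hz"))
}

#' Compact battery for cross-validation studies
#'
#' Eight short protocols (three clamp levels, two square pulses, three
#' pairings) keeping leave-one-out refits affordable.
#'
#' @return A list of [protocol_spec()]s.
#' @export
crossval_protocol_battery <- function() {
  list(
    protocol_spec("clamp", clamp_mv = 8,  repetitions = 5, frequency_hz = 20),
    protocol_spec("clamp", clamp_mv = 14, repetitions = 5, frequency_hz = 20),
    protocol_spec("clamp", clamp_mv = 22, repetitions = 5, frequency_hz = 20),
    protocol_spec("pulse", pulse = list(delta_u = 25, T = 10, spike_offset = 5),
                  repetitions = 30),
    protocol_spec("pulse", pulse = list(delta_u = 12, T = 25, spike_offset = 35),
                  repetitions = 30),
    protocol_spec("pairing", interval_ms = 10,  repetitions = 10,
                  frequency_hz = 20),
    protocol_spec("pairing", interval_ms = -10, repetitions = 10,
                  frequency_hz = 20),
    protocol_spec("pairing", interval_ms = 10,  repetitions = 6,
                  frequency_hz = 10, n_post = 3, post_freq_hz = 200))
}

#' Reference ground-truth parameters for synthetic validation studies
#'
#' A fixed, well-interior point of the fitting box used as the generating
#' ("true") parameter set in the package's self-validation studies
#' (parameter recovery, cross-validation, veto ablation).  The veto strength
#' is deliberately moderate so that the LTP-on-LTD interaction is engaged
#' but not saturated.
#'
#' @return A [plasticity_params()] object.
#' @export
synthetic_reference_params <- function() {
  plasticity_params(tau_x = 8, tau_plus = 10, tau_minus = 25,
                    theta_plus = 12, theta_0 = 5.5,
                    A_LTP = 4e-4, A_LTD = 6e-4,
                    b_theta = 5e3, tau_theta = 12)
}

#' Synthetic labelled dataset with known ground truth
#'
#' Realizes a protocol battery as traces and spike trains, computes the
#' model-predicted relative weight change under `true_params`, and adds
#' zero-mean Gaussian noise of sd `noise_sd` to produce synthetic
#' "experimental" outcomes.  Reproducible under a fixed seed; the global RNG
#' state is restored on exit.
#'
#' @param true_params a [plasticity_params()] object.
#' @param battery list of [protocol_spec()]s (default
#'   [default_protocol_battery()]).
#' @param noise_sd standard deviation of the outcome noise (fraction of
#'   initial weight); `0` gives exactly the model predictions.
#' @param seed integer seed for the noise.
#' @param kernels a [kernel_params()] object.
#' @param dt sample interval (ms).
#' @param w_init initial weight.
#' @return A [vbp_dataset()].
#' @export
make_synthetic_dataset <- function(true_params,
                                   battery = default_protocol_battery(),
                                   noise_sd = 0.05, seed = 1,
                                   kernels = kernel_params(), dt = 0.1,
                                   w_init = 0.5) {
  if (!length(battery)) stop("empty protocol battery")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  validate_params(true_params)
  comps <- lapply(battery, make_protocol, kernels = kernels, dt = dt)
  pred <- vapply(comps, function(cc)
    simulate_trial_mixture(cc, true_params, w_init = w_init)$relative_change,
    numeric(1))
  noise <- with_seed(seed, stats::rnorm(length(pred), 0, noise_sd))
  records <- lapply(seq_along(battery), function(i)
    protocol_record(battery[[i]]$id, comps[[i]], pred[i] + noise[i]))
  vbp_dataset(records)
}

# evaluate expr with a fixed RNG seed, restoring the global state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
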