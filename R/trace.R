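# Voltage traces and presynaptic spike trains.

#' Uniformly sampled dendritic voltage trace
#'
#' A voltage trace holds samples of the dendritic membrane potential near the
#' synapse, expressed in mV *relative to rest* (the resting potential is
#' shifted to 0; see [read_trace()] for baseline handling of recorded data),
#' on a uniform grid with step `dt`.
#'
#' @param values numeric vector of voltage samples (mV relative to rest).
#' @param dt sample interval (ms).
#' @param t0 time of the first sample (ms).
#' @return An object of class `"voltage_trace"`.
#' @export
#' @examples
#' tr <- voltage_trace(rep(0, 1001), dt = 0.1)
#' trace_duration(tr)
voltage_trace <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a voltage trace needs at least two samples")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number")
  if (!all(is.finite(values))) {
    i <- which(!is.finite(values))[1L]
    stop("non-finite voltage sample at index ", i,
         " (t = ", t0 + (i - 1) * dt, " ms)")
  }
  structure(list(values = values, dt = dt, t0 = t0), class = "voltage_trace")
}

#' @rdname voltage_trace
#' @param trace a `voltage_trace`.
#' @return `trace_duration()`: the spanned time `dt * (n - 1)` in ms.
#' @export
trace_duration <- function(trace) {
  trace$dt * (length(trace$values) - 1L)
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("Voltage trace: %d samples, dt = %g ms, span [%g, %g] ms, range [%.3g, %.3g] mV\n",
              length(x$values), x$dt, x$t0, x$t0 + trace_duration(x),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Presynaptic spike train
#'
#' Sorted presynaptic spike times in ms.  Each spike increments the glutamate
#' trace `x_bar` of the plasticity rule by 1.
#'
#' @param times numeric vector of spike times (ms); must be strictly
#'   increasing.  May be empty.
#' @return An object of class `"spike_train"`.
#' @export
spike_train <- function(times = numeric()) {
  times <- as.numeric(times)
  if (anyNA(times) || (length(times) && !all(is.finite(times))))
    stop("spike times must be finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  structure(list(times = times), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Spike train: %d spike%s", n, if (n == 1L) "" else "s"))
  if (n) cat(sprintf(" in [%g, %g] ms", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

as_spike_train <- function(x) {
  if (inherits(x, "spike_train")) x else spike_train(x)
}

as_voltage_trace <- function(x) {
  if (inherits(x, "voltage_trace")) return(x)
  stop("expected a voltage_trace object")
}

# Assign each spike to an integration step.  Step n covers (t_{n-1}, t_n]
# with t_n = t0 + n*dt; a spike exactly at t0 is attributed to step 1.
bin_spikes <- function(times, t0, dt, n_steps) {
  if (!length(times)) return(integer(n_steps))
  k <- (times - t0) / dt
  idx <- ceiling(k - 1e-9)
  idx[idx < 1L] <- ifelse(k[idx < 1L] > -1e-9, 1L, 0L)
  bad <- idx < 1L | idx > n_steps
  if (any(bad))
    stop("spike at t = ", times[which(bad)[1L]],
         " ms lies outside the trace span")
  tabulate(idx, nbins = n_steps)
}
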