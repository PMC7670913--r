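# Shared fixtures: parameter sets and small protocol collections, built in
# code at test time.

# voltage-clamp parameter set with a linear voltage-plasticity relation
fig_linear_params <- function() vbp_preset_params("clamp-linear")

# veto-free variant for closed-form checks
no_veto_params <- function(u_theta_plus = 10) {
  plasticity_params(tau_x = 5, tau_plus = 6, tau_minus = 15,
                    theta_plus = u_theta_plus, theta_0 = 5,
                    A_LTP = 1e-4, A_LTD = 1e-4, b_theta = 0, tau_theta = 14)
}

# draw a random in-bounds parameter set away from the box edges
random_params <- function() {
  plasticity_params(runif(1, 5, 20), runif(1, 5, 25), runif(1, 10, 40),
                    runif(1, 9, 14), runif(1, 3, 7),
                    10^runif(1, -3.5, -2.5), 10^runif(1, -3.5, -2.5),
                    runif(1, 0, 5e4), runif(1, 5, 40))
}

# a random short pairing protocol (single component)
random_pairing_component <- function() {
  spec <- protocol_spec("pairing", interval_ms = sample(c(-10, 0, 10), 1),
                        repetitions = 3, frequency_hz = 10)
  make_protocol(spec, kernels = kernel_params(epsp_amp = 10), dt = 0.1)[[1]]
}

# tiny three-protocol battery for cheap fitting-machinery tests
tiny_battery <- function() {
  list(
    protocol_spec("clamp", clamp_mv = 8,  repetitions = 4, frequency_hz = 20),
    protocol_spec("clamp", clamp_mv = 18, repetitions = 4, frequency_hz = 20),
    protocol_spec("pulse", pulse = list(delta_u = 20, T = 10, spike_offset = 5),
                  repetitions = 20))
}

# linearly interpolate a trace onto a refined grid (shares the underlying
# continuous-time input with fine_grid_reference)
refine_trace <- function(tr, factor = 2) {
  t <- tr$t0 + (seq_along(tr$values) - 1L) * tr$dt
  g <- seq(t[1L], t[length(t)], by = tr$dt / factor)
  voltage_trace(approx(t, tr$values, xout = g)$y, tr$dt / factor, tr$t0)
}

rel_err <- function(a, b, floor = 1e-6) abs(a - b) / max(abs(b), floor)
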