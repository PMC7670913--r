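# Synthetic trace generation and the labelled-dataset generator.

test_that("clamp traces and protocols have the stated shape", {
  tr <- make_clamp_trace(0, 50, 0.1)
  expect_true(all(tr$values == 0))
  expect_length(tr$values, 501L)
  pr <- make_clamp_protocol(12, n_pulses = 10, frequency_hz = 5, lead = 100,
                            tail = 50)
  expect_length(pr$spikes$times, 10L)
  expect_equal(diff(pr$spikes$times), rep(200, 9))
  expect_true(all(pr$trace$values == 12))
  expect_gte(trace_duration(pr$trace), max(pr$spikes$times) + 50)
})

test_that("square-pulse protocols place pulse and spike as requested", {
  pr <- make_square_pulse_protocol(15, 20, 30)   # spike 10 ms after pulse end
  t <- (seq_along(pr$trace$values) - 1L) * 0.1
  on <- pr$trace$values > 0
  expect_equal(max(pr$trace$values), 15)
  expect_equal(sum(on) * 0.1, 20, tolerance = 0.02)
  expect_equal(pr$spikes$times - min(t[on]), 30)
  # zero-height pulse changes nothing for any placement
  p <- fig_linear_params()
  for (off in c(-10, 10, 30)) {
    pr0 <- make_square_pulse_protocol(0, 20, off)
    expect_identical(vbp_simulate(pr0$trace, pr0$spikes, p)$relative_change, 0)
  }
  # very early spikes extend the lead time instead of falling off the trace
  pr_e <- make_square_pulse_protocol(10, 5, -100)
  expect_gte(pr_e$spikes$times, 0)
  expect_silent(vbp_simulate(pr_e$trace, pr_e$spikes, fig_linear_params()))
})

test_that("pairing traces superpose kernels linearly and cover all events", {
  k0 <- kernel_params(epsp_amp = 0, bap_amp = 0, dspike_amp = 0)
  spec <- protocol_spec("pairing", interval_ms = 10, repetitions = 1)
  flat <- make_protocol(spec, kernels = k0)[[1]]
  expect_true(all(flat$trace$values == 0))
  expect_length(flat$spikes$times, 1L)
  # EPSP-only plus bAP-only equals the joint trace pointwise
  ke <- kernel_params(bap_amp = 0)
  kb <- kernel_params(epsp_amp = 0)
  kk <- kernel_params()
  tr_e <- make_protocol(spec, kernels = ke)[[1]]$trace$values
  tr_b <- make_protocol(spec, kernels = kb)[[1]]$trace$values
  tr_eb <- make_protocol(spec, kernels = kk)[[1]]$trace$values
  expect_equal(tr_e + tr_b, tr_eb, tolerance = 1e-12)
  # traces relax back toward rest by the end (slow after-depolarization tail)
  expect_lt(abs(tr_eb[length(tr_eb)]), 0.01)
  # period shorter than the spike pattern is rejected
  expect_error(make_protocol(protocol_spec("pairing", interval_ms = 10,
                                           repetitions = 3,
                                           frequency_hz = 100,
                                           n_post = 3, post_freq_hz = 100)),
               "shorter")
})

test_that("residual depolarization accumulates at high pairing frequency", {
  # with a slow after-depolarization the filtered voltage at the 5th pairing
  # starts higher at 40 Hz than at 0.1-like low frequency
  k <- kernel_params(adp_tau = 40)
  p <- fig_linear_params()
  peak_at_rep <- function(freq) {
    spec <- protocol_spec("pairing", interval_ms = 10, repetitions = 5,
                          frequency_hz = freq, per_trial = FALSE)
    cc <- make_protocol(spec, kernels = k)[[1]]
    s <- vbp_simulate(cc$trace, cc$spikes, p, record_trajectory = TRUE)
    base <- cc$spikes$times[5]
    win <- s$trajectory$time >= base & s$trajectory$time <= base + 1000 / freq / 2
    max(s$trajectory$u_bar_plus[win])
  }
  expect_gt(peak_at_rep(40), peak_at_rep(1))
})

test_that("dataset generator is reproducible, unbiased at zero noise, and chi-square at positive noise", {
  truth <- synthetic_reference_params()
  batt <- tiny_battery()
  d0 <- make_synthetic_dataset(truth, batt, noise_sd = 0, seed = 5)
  expect_equal(vapply(d0, `[[`, numeric(1), "dw_exp"),
               predict_dw(truth, d0), tolerance = 1e-14)
  d1 <- make_synthetic_dataset(truth, batt, noise_sd = 0.05, seed = 9)
  d2 <- make_synthetic_dataset(truth, batt, noise_sd = 0.05, seed = 9)
  expect_identical(vapply(d1, `[[`, numeric(1), "dw_exp"),
                   vapply(d2, `[[`, numeric(1), "dw_exp"))
  expect_error(make_synthetic_dataset(truth, list(), 0, 1), "empty")
  # SE at the true parameters has mean n*sigma^2 across noise replicates
  n_prot <- length(batt); sigma <- 0.05; n_rep <- 200
  pred <- predict_dw(truth, d0)
  ses <- vapply(seq_len(n_rep), function(r) {
    d <- make_synthetic_dataset(truth, batt, noise_sd = sigma, seed = 1000 + r)
    compute_se(pred, vapply(d, `[[`, numeric(1), "dw_exp"))
  }, numeric(1))
  expect_gt(length(unique(round(ses, 10))), n_rep / 2)
  mu <- n_prot * sigma^2
  se_of_mean <- sqrt(2 * n_prot) * sigma^2 / sqrt(n_rep)
  expect_lt(abs(mean(ses) - mu), 3 * se_of_mean)
})

test_that("generated batteries satisfy the trace invariants", {
  for (spec in c(default_protocol_battery(), crossval_protocol_battery())) {
    comps <- make_protocol(spec)
    for (cc in comps) {
      expect_s3_class(cc$trace, "voltage_trace")
      expect_true(all(is.finite(cc$trace$values)))
      if (length(cc$spikes$times))
        expect_gte(trace_duration(cc$trace) + cc$trace$t0,
                   max(cc$spikes$times) + 50)
    }
  }
})
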