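# The plasticity rule itself: update order, gating, decomposition, veto.

test_that("sub-threshold voltage and silent presynapse produce exactly zero change", {
  p <- fig_linear_params()
  # u = 0 throughout: both rectifiers stay closed since theta_plus > theta_0 > 0
  s <- vbp_simulate(voltage_trace(rep(0, 10001), 0.1),
                    spike_train(c(100, 200)), p)
  expect_identical(s$relative_change, 0)
  expect_identical(s$w_final, s$w_initial)
  # no presynaptic spikes: x_bar = 0 gates all plasticity
  s <- vbp_simulate(voltage_trace(rep(30, 10001), 0.1), spike_train(), p)
  expect_identical(s$relative_change, 0)
  # voltage never above theta_0
  s <- vbp_simulate(voltage_trace(rep(4, 10001), 0.1),
                    spike_train(c(100, 500)), p)
  expect_identical(s$relative_change, 0)
})

test_that("scalar step and vectorized integration are bit-identical", {
  set.seed(42)
  dt <- 0.1
  n <- 400
  v <- c(0, cumsum(rnorm(n)))
  tr <- voltage_trace(v, dt)
  sp <- spike_train(sort(runif(6, 0, 35)))
  p <- fig_linear_params()
  sim <- vbp_simulate(tr, sp, p, record_trajectory = TRUE)
  counts <- tabulate(ceiling((sp$times) / dt - 1e-9), nbins = n)
  st <- new_model_state()
  for (i in seq_len(n)) st <- plasticity_step(st, v[i + 1], counts[i], dt, p)
  expect_identical(st$w, sim$w_final)
  expect_identical(st$x_bar, sim$trajectory$x_bar[n])
  expect_identical(st$theta_var, sim$trajectory$theta_var[n])
  expect_identical(st$u_bar_plus, sim$trajectory$u_bar_plus[n])
  # decomposition holds along the whole trajectory
  expect_equal(sim$trajectory$w,
               sim$w_initial + sim$trajectory$w_ltp - sim$trajectory$w_ltd)
  # repeated run is bit-identical
  expect_identical(sim$w_final, vbp_simulate(tr, sp, p)$w_final)
})

test_that("equilibrated clamp with a single spike matches the closed-form LTP integral", {
  p <- no_veto_params()
  u0 <- 20
  tr <- make_clamp_trace(u0, 2000, 0.1)
  s <- vbp_simulate(tr, spike_train(1000), p)  # filters equilibrated by 1000 ms
  expect_equal(s$w_ltp, analytic_single_spike_ltp(u0, p), tolerance = 1e-6)
  # at the rectifier boundary the closed form is zero
  expect_identical(analytic_single_spike_ltp(p[["theta_plus"]], p), 0)
  # linear in tau_x
  p2 <- no_veto_params(); p2[["tau_x"]] <- 2 * p2[["tau_x"]]
  expect_equal(analytic_single_spike_ltp(u0, p2),
               2 * analytic_single_spike_ltp(u0, p), tolerance = 1e-12)
})

test_that("raising b_theta never increases depression and never touches potentiation", {
  set.seed(11)
  for (k in 1:20) {
    cc <- random_pairing_component()
    base <- random_params()
    prev_ltd <- Inf
    ltp0 <- NULL
    for (b in c(0, 1e3, 1e4, 1e5)) {
      p <- base
      p[["b_theta"]] <- b
      s <- vbp_simulate(cc$trace, cc$spikes, p)
      expect_lte(s$w_ltd, prev_ltd + 1e-15)
      if (is.null(ltp0)) ltp0 <- s$w_ltp else expect_identical(s$w_ltp, ltp0)
      prev_ltd <- s$w_ltd
    }
  }
})

test_that("pointwise-larger voltage never decreases potentiation when the veto is off", {
  set.seed(12)
  dt <- 0.1
  for (k in 1:10) {
    p <- random_params()
    p[["b_theta"]] <- 0
    cc <- random_pairing_component()
    lift <- voltage_trace(cc$trace$values + runif(1, 0.5, 5), dt)
    s0 <- vbp_simulate(cc$trace, cc$spikes, p)
    s1 <- vbp_simulate(lift, cc$spikes, p)
    expect_gte(s1$w_ltp, s0$w_ltp - 1e-15)
  }
})

test_that("voltage filters have unit DC gain and first-order step response", {
  p <- fig_linear_params()
  u0 <- 17
  tr <- make_clamp_trace(u0, 12 * p[["tau_minus"]], 0.1)
  s <- vbp_simulate(tr, spike_train(), p, record_trajectory = TRUE)
  n <- nrow(s$trajectory)
  expect_lt(abs(s$trajectory$u_bar_plus[n] - u0), 1e-4 * u0)
  expect_lt(abs(s$trajectory$u_bar_minus[n] - u0), 1e-4 * u0)
  # after one time constant the step response is u0 (1 - 1/e), within 1%
  i <- round(p[["tau_plus"]] / 0.1)
  expect_lt(abs(s$trajectory$u_bar_plus[i] - u0 * (1 - exp(-1))),
            0.01 * u0 * (1 - exp(-1)))
})

test_that("spike binning respects the (t, t+dt] convention and trace span", {
  p <- fig_linear_params()
  tr <- make_clamp_trace(20, 100, 0.1)
  # spike exactly at t0 is attributed to the first step, not rejected
  expect_silent(vbp_simulate(tr, spike_train(0), p))
  expect_error(vbp_simulate(tr, spike_train(100.2), p), "outside")
  expect_error(vbp_simulate(tr, spike_train(-3), p), "outside")
  expect_error(plasticity_step(new_model_state(), NaN, 0, 0.1,
                               fig_linear_params()), "non-finite")
  expect_error(plasticity_step(new_model_state(), 1, 0, -0.1,
                               fig_linear_params()), "dt")
})

test_that("trial mixtures decompose into repetition-weighted independent trials", {
  p <- vbp_preset_params("ca3-subthreshold")
  spec <- protocol_spec("pairing", interval_ms = 10, repetitions = 60,
                        frequency_hz = 0.1,
                        composition = c(linear = 2 / 3, supra = 1 / 3))
  comps <- make_protocol(spec)
  expect_length(comps, 2L)
  expect_equal(sum(vapply(comps, `[[`, numeric(1), "reps")), 60)
  mix <- simulate_trial_mixture(comps, p)
  parts <- vapply(comps, function(cc) {
    s <- vbp_simulate(cc$trace, cc$spikes, p)
    cc$reps * (s$w_ltp - s$w_ltd)
  }, numeric(1))
  expect_equal(mix$w_final - mix$w_initial, sum(parts), tolerance = 1e-14)
  # a single component with one repetition is plain integration
  one <- simulate_trial_mixture(list(list(trace = comps[[1]]$trace,
                                          spikes = comps[[1]]$spikes,
                                          reps = 1)), p)
  expect_identical(one$w_final,
                   vbp_simulate(comps[[1]]$trace, comps[[1]]$spikes, p)$w_final)
  # mismatched dt is rejected
  bad <- list(list(trace = make_clamp_trace(1, 10, 0.1), spikes = numeric(), reps = 1),
              list(trace = make_clamp_trace(1, 10, 0.2), spikes = numeric(), reps = 1))
  expect_error(simulate_trial_mixture(bad, p), "dt")
})

test_that("only trials crossing the LTP threshold drive the mixture outcome", {
  # linear trials stay below theta_0 after filtering; supralinear trials cross
  # theta_plus: the net sign must follow the supralinear contribution
  p <- fig_linear_params()
  k <- kernel_params(epsp_amp = 2, bap_amp = 0, dspike_amp = 35)
  spec <- protocol_spec("pairing", interval_ms = 10, repetitions = 60,
                        frequency_hz = 0.1, n_post = 0,
                        composition = c(linear = 2 / 3, supra = 1 / 3))
  comps <- make_protocol(spec, kernels = k)
  lin <- comps[[which(vapply(comps, `[[`, numeric(1), "reps") == 40)]]
  expect_identical(vbp_simulate(lin$trace, lin$spikes, p)$relative_change, 0)
  mix <- simulate_trial_mixture(comps, p)
  sup <- comps[[which(vapply(comps, `[[`, numeric(1), "reps") == 20)]]
  s_sup <- vbp_simulate(sup$trace, sup$spikes, p)
  expect_gt(abs(s_sup$relative_change), 0)
  expect_identical(sign(mix$relative_change), sign(s_sup$relative_change))
})
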