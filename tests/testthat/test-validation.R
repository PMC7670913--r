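# Model-criticism layer on small problems.

test_that("sensitivity analysis has 18 entries and respects feasibility", {
  truth <- synthetic_reference_params()
  dat <- make_synthetic_dataset(truth, tiny_battery(), noise_sd = 0.05,
                                seed = 6)
  sa <- sensitivity_analysis(truth, dat, delta = 0.05)
  expect_equal(nrow(sa), 18L)
  expect_setequal(unique(sa$direction), c("up", "down"))
  # delta = 0 leaves the objective untouched
  sa0 <- sensitivity_analysis(truth, dat, delta = 0)
  expect_true(all(sa0$delta_se == 0))
  # a theta_0 increase that would cross theta_plus gets clipped and flagged
  p_edge <- plasticity_params(8, 10, 25, 12, 11.9, 4e-4, 6e-4, 0, 12)
  sa_e <- sensitivity_analysis(p_edge, dat, delta = 0.05)
  expect_true(sa_e$clipped[sa_e$parameter == "theta_0" &
                           sa_e$direction == "up"])
})

test_that("veto parameters are inert on datasets that never trigger LTP", {
  p <- fig_linear_params()
  # clamp levels between theta_0 and theta_plus: LTD only, no LTP
  batt <- list(protocol_spec("clamp", clamp_mv = 7, repetitions = 4,
                             frequency_hz = 10),
               protocol_spec("clamp", clamp_mv = 9, repetitions = 4,
                             frequency_hz = 10))
  dat <- make_synthetic_dataset(p, batt, noise_sd = 0, seed = 1)
  sa <- sensitivity_analysis(p, dat, delta = 0.05)
  veto_rows <- sa$parameter %in% c("b_theta", "tau_theta")
  expect_true(all(sa$delta_se[veto_rows] == 0))
})

test_that("veto ablation keeps the nested-model inequality and detects its own truth", {
  truth_b0 <- synthetic_reference_params()
  truth_b0[["b_theta"]] <- 0
  dat <- make_synthetic_dataset(truth_b0, tiny_battery(), noise_sd = 0,
                                seed = 7)
  ab <- suppressWarnings(veto_ablation(dat, n_starts = 2, seed = 2,
                                       maxiter = 20))
  expect_lte(ab$error_with_veto, ab$error_without_veto + 1e-12)
  expect_identical(coef(ab$fit_without)[["b_theta"]], 0)
})

test_that("leave-one-out on duplicated protocols returns identical folds with zero CoV", {
  truth <- synthetic_reference_params()
  one <- make_synthetic_dataset(truth, tiny_battery()[1:2], noise_sd = 0,
                                seed = 1)
  dup <- vbp_dataset(lapply(1:4, function(i)
    protocol_record(paste0("p", i), one[[1]]$components, one[[1]]$dw_exp)))
  cv <- suppressWarnings(
    loo_crossval(dup, n_starts = 2, seed = 3, maxiter = 10,
                 screen_factor = 1, polish_top = 0, warm_start = FALSE))
  expect_equal(nrow(cv$per_fold), 4L)
  # every fold trains on an identical multiset of outcomes
  expect_true(all(apply(cv$params, 2, function(v) diff(range(v)) == 0)))
  expect_true(all(cv$param_cov == 0 | is.na(cv$param_cov)))
})

test_that("voltage-plasticity scan shows the three regimes with the clamp-linear set", {
  p <- fig_linear_params()
  vc <- voltage_plasticity_curve(p, n_pulses = 20, frequency_hz = 10,
                                 clamp_levels = seq(-2, 30, by = 1))
  cu <- vc$curve
  expect_true(all(cu$percent[cu$u <= 4] == 100))        # no change near rest
  expect_lt(cu$percent[cu$u == 8], 100)                 # depression above theta_0
  expect_gt(cu$percent[cu$u == 30], 100)                # potentiation at the top
  expect_lte(abs(vc$no_change_boundary - p[["theta_0"]]), 1)
  expect_true(is.finite(vc$ltd_ltp_crossover))
})

test_that("triplet predictions carry the expected sign structure with tuned kernels", {
  p <- vbp_preset_params("l5-l5")
  k0 <- kernel_params(epsp_amp = 0, bap_amp = 0, dspike_amp = 0)
  tp0 <- triplet_prediction(p, kernels = k0, repetitions = 2)
  expect_true(all(tp0$percent == 100))
  k <- kernel_params(epsp_amp = 6, bap_amp = 60, adp_frac = 0.3,
                     adp_tau = 30)
  tp <- triplet_prediction(p, kernels = k, intervals = c(5, 10),
                           repetitions = 30)
  expect_equal(nrow(tp), 8L)
  post_pre <- tp$percent[tp$protocol == "post-pre"]
  expect_true(all(post_pre < 100))                      # LTD for both intervals
  # adding a trailing postsynaptic spike only adds depolarization and LTP
  for (iv in c(5, 10)) {
    pp  <- tp$percent[tp$protocol == "post-pre" & tp$interval_ms == iv]
    ppp <- tp$percent[tp$protocol == "post-pre-post" & tp$interval_ms == iv]
    expect_gte(ppp, pp)
  }
})
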