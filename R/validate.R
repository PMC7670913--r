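# Model criticism: leave-one-out cross-validation, sensitivity analysis,
# veto ablation, voltage--plasticity regime scans and triplet predictions.

#' Leave-one-out cross-validation of the rule
#'
#' For each protocol outcome, refits the rule on all remaining outcomes and
#' evaluates the squared prediction error on the held-out one.  Reports the
#' median training error (normalized by the training-set size), the median
#' test error, and the per-parameter coefficient of variation across folds
#' (100 * population sd / mean) -- a direct read-out of which parameters the
#' data identify well.
#'
#' @param data a [vbp_dataset()] with at least 3 outcomes.
#' @param warm_start if `TRUE`, a single full-data multi-start fit is run
#'   first and its solution is added to every fold's start list.  This
#'   removes optimizer-lottery variation between folds (the parameter
#'   coefficient of variation then reads out identifiability rather than
#'   search noise) but leaks information about the held-out outcome into
#'   the fold through the start point, biasing the test error downward; it
#'   is therefore off by default.
#' @inheritParams vbp_fit
#' @return An object of class `"vbp_loo"`: list with `per_fold` (data frame
#'   with held-out id, training normalized error, test squared error and the
#'   fitted parameters), `median_train_norm`, `median_test`, `param_cov`.
#' @export
loo_crossval <- function(data, bounds = default_param_bounds(), n_starts = 5,
                         seed = 1, w_init = 0.5, maxiter = 25,
                         warm_start = FALSE, ...) {
  if (!inherits(data, "vbp_dataset")) stop("data must be a vbp_dataset")
  n <- length(data)
  if (n < 3L) stop("leave-one-out needs at least 3 outcomes")
  warm <- list()
  if (warm_start) {
    full <- tryCatch(
      vbp_fit(data, bounds = bounds, n_starts = n_starts, seed = seed,
              w_init = w_init, maxiter = maxiter, ...),
      error = function(e) NULL)
    if (!is.null(full)) warm <- list(full$params)
  }
  rows <- vector("list", n)
  par_mat <- matrix(NA_real_, n, 9L, dimnames = list(NULL, .PAR_NAMES))
  for (i in seq_len(n)) {
    held <- data[[i]]
    fold <- tryCatch(
      vbp_fit(data[-i], bounds = bounds, n_starts = n_starts, seed = seed,
              w_init = w_init, maxiter = maxiter, extra_starts = warm, ...),
      error = function(e) e)
    if (inherits(fold, "error")) {
      rows[[i]] <- data.frame(id = held$id, train_norm = NA_real_,
                              test_se = NA_real_, failed = TRUE)
      next
    }
    pred <- predict_dw(fold$params, held, w_init = w_init)
    rows[[i]] <- data.frame(id = held$id,
                            train_norm = normalized_error(fold$lse, n - 1L),
                            test_se = (pred - held$dw_exp)^2,
                            failed = FALSE)
    par_mat[i, ] <- as.numeric(fold$params)
  }
  per_fold <- do.call(rbind, rows)
  cov <- apply(par_mat, 2L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    100 * stats::sd(v) * sqrt((length(v) - 1) / length(v)) / mean(v)
  })
  structure(list(per_fold = per_fold,
                 median_train_norm = stats::median(per_fold$train_norm,
                                                   na.rm = TRUE),
                 median_test = stats::median(per_fold$test_se, na.rm = TRUE),
                 param_cov = cov,
                 params = par_mat), class = "vbp_loo")
}

#' @export
print.vbp_loo <- function(x, ...) {
  cat("Leave-one-out cross-validation\n")
  cat(sprintf("  folds: %d (failed: %d)\n", nrow(x$per_fold),
              sum(x$per_fold$failed)))
  cat(sprintf("  median training error (normalized): %.4g\n",
              x$median_train_norm))
  cat(sprintf("  median test squared error:          %.4g\n", x$median_test))
  cat("  parameter coefficient of variation (%):\n")
  print(round(x$param_cov, 1L))
  invisible(x)
}

#' One-at-a-time parameter sensitivity of the fitting error
#'
#' Perturbs each of the nine parameters by `+delta` and `-delta` (relative),
#' one at a time, and reports the change in squared error
#' `delta_SE = SE(perturbed) - SE(params)` on the given dataset.  A
#' perturbation of `theta_0` that would violate `theta_plus > theta_0` is
#' clipped to feasibility and flagged.
#'
#' @param params a [plasticity_params()] object (e.g. a fit's best set).
#' @param data a [vbp_dataset()].
#' @param delta relative perturbation (default 0.05 = 5%).
#' @param w_init initial weight.
#' @return A data frame with 18 rows and columns `parameter`, `direction`,
#'   `value`, `delta_se`, `clipped`.
#' @export
sensitivity_analysis <- function(params, data, delta = 0.05, w_init = 0.5) {
  validate_params(params)
  if (!inherits(data, "vbp_dataset")) stop("data must be a vbp_dataset")
  cache <- .cache_dataset(data)
  obs <- vapply(data, `[[`, numeric(1), "dw_exp")
  base_se <- compute_se(.predict_cached(params, cache, w_init), obs)
  out <- expand.grid(parameter = .PAR_NAMES, direction = c("up", "down"),
                     stringsAsFactors = FALSE)
  out$value <- NA_real_; out$delta_se <- NA_real_; out$clipped <- FALSE
  for (r in seq_len(nrow(out))) {
    p <- as.numeric(params); names(p) <- names(params)
    nm <- out$parameter[r]
    fac <- if (out$direction[r] == "up") 1 + delta else 1 - delta
    p[[nm]] <- p[[nm]] * fac
    if (p[["theta_0"]] >= p[["theta_plus"]]) {
      p[["theta_0"]] <- p[["theta_plus"]] - 1e-6
      out$clipped[r] <- TRUE
    }
    out$value[r] <- p[[nm]]
    out$delta_se[r] <- compute_se(.predict_cached(p, cache, w_init), obs) -
      base_se
  }
  attr(out, "base_se") <- base_se
  out
}

#' Veto ablation: refit with the LTP-on-LTD interaction disabled
#'
#' Runs two independent multi-start fits: one with the veto strength
#' `b_theta` free, one with it fixed at 0 (no LTP-on-LTD interaction; the
#' then-inert `tau_theta` is also pinned).  The veto-free solution is added
#' to the free fit's start list, so the nested-model inequality
#' `error_with_veto <= error_without_veto` holds by construction.
#'
#' @inheritParams vbp_fit
#' @return A list with `error_with_veto`, `error_without_veto`, `ratio`
#'   (with/without), and the two `vbp_fit` objects `fit_with`,
#'   `fit_without`.
#' @export
veto_ablation <- function(data, bounds = default_param_bounds(), n_starts = 5,
                          seed = 1, w_init = 0.5, maxiter = 40, ...) {
  fit_wo <- vbp_fit(data, bounds = bounds, n_starts = n_starts, seed = seed,
                    w_init = w_init, maxiter = maxiter,
                    fixed = c(b_theta = 0, tau_theta = 10), ...)
  start_wo <- as.numeric(fit_wo$params)
  names(start_wo) <- names(fit_wo$params)
  start_wo[["b_theta"]] <- 0
  fit_w <- vbp_fit(data, bounds = bounds, n_starts = n_starts, seed = seed,
                   w_init = w_init, maxiter = maxiter,
                   extra_starts = list(as_plasticity_params(start_wo)), ...)
  list(error_with_veto = fit_w$lse,
       error_without_veto = fit_wo$lse,
       ratio = fit_w$lse / fit_wo$lse,
       fit_with = fit_w,
       fit_without = fit_wo)
}

#' Voltage dependence of plasticity under clamp
#'
#' Pairs a presynaptic pulse train with constant voltage clamp at each level
#' and reports the final synaptic strength as a percentage of its initial
#' value, together with the detected regime boundaries: the largest clamp
#' level still producing no change (onset of depression, expected at
#' `theta_0`) and the level at which depression turns into potentiation
#' (linear interpolation between grid levels).
#'
#' @param params a [plasticity_params()] object.
#' @param n_pulses number of presynaptic stimulations per level.
#' @param frequency_hz stimulation frequency (Hz).
#' @param clamp_levels sorted clamp levels (mV relative to rest); the default
#'   scans -5..30 mV in 0.5 mV steps.
#' @param dt integration step (ms).
#' @param w_init initial weight.
#' @return An object of class `"vbp_vcurve"`: list with `curve` (data frame
#'   `u`, `dw`, `percent`), `no_change_boundary`, `ltd_ltp_crossover`.
#' @export
voltage_plasticity_curve <- function(params, n_pulses = 100, frequency_hz = 2,
                                     clamp_levels = seq(-5, 30, by = 0.5),
                                     dt = 0.1, w_init = 0.5) {
  validate_params(params)
  if (is.unsorted(clamp_levels, strictly = TRUE))
    stop("clamp_levels must be strictly increasing")
  dw <- vapply(clamp_levels, function(u0) {
    pr <- make_clamp_protocol(u0, n_pulses = n_pulses,
                              frequency_hz = frequency_hz, dt = dt)
    vbp_simulate(pr$trace, pr$spikes, params,
                 w_init = w_init)$relative_change
  }, numeric(1))
  curve <- data.frame(u = clamp_levels, dw = dw, percent = 100 * (1 + dw))
  tol <- 1e-12
  nz <- which(abs(dw) > tol)
  no_change <- if (length(nz) && nz[1L] > 1L) clamp_levels[nz[1L] - 1L]
    else if (!length(nz)) clamp_levels[length(clamp_levels)] else NA_real_
  crossover <- NA_real_
  if (length(nz)) {
    s <- sign(dw)
    idx <- which(s[-length(s)] < 0 & s[-1L] >= 0)
    if (length(idx)) {
      i <- idx[1L]
      crossover <- clamp_levels[i] - dw[i] *
        (clamp_levels[i + 1L] - clamp_levels[i]) / (dw[i + 1L] - dw[i])
    }
  }
  structure(list(curve = curve, no_change_boundary = no_change,
                 ltd_ltp_crossover = crossover,
                 n_pulses = n_pulses, frequency_hz = frequency_hz),
            class = "vbp_vcurve")
}

#' @export
print.vbp_vcurve <- function(x, ...) {
  cat(sprintf("Voltage-plasticity curve: %d pulses at %g Hz, %d clamp levels\n",
              x$n_pulses, x$frequency_hz, nrow(x$curve)))
  cat(sprintf("  no-change boundary: %g mV\n  LTD->LTP crossover: %g mV\n",
              x$no_change_boundary, x$ltd_ltp_crossover))
  invisible(x)
}

#' @export
plot.vbp_vcurve <- function(x, ...) {
  graphics::plot(x$curve$u, x$curve$percent, type = "l",
                 xlab = "clamp level (mV above rest)",
                 ylab = "w (% of initial)", ...)
  graphics::abline(h = 100, col = "grey70", lty = 2)
  invisible(x)
}

#' Predicted plasticity for spike pairs and triplets
#'
#' Builds surrogate dendritic traces (EPSP kernel per presynaptic spike, bAP
#' waveform per postsynaptic spike) for pair and triplet protocols --
#' pre-post, post-pre, pre-post-pre and post-pre-post, with the stated
#' interval between consecutive spikes -- and reports the final weight as a
#' percentage of its initial value.  With surrogate kernels the output is a
#' qualitative prediction: the sign structure, not the exact percentages,
#' is the meaningful content.
#'
#' @param params a [plasticity_params()] object.
#' @param kernels a [kernel_params()] object for the surrogate waveforms.
#' @param intervals spike intervals to probe (ms).
#' @param repetitions number of repetitions per protocol.
#' @param frequency_hz repetition frequency (Hz).
#' @param dt integration step (ms).
#' @param w_init initial weight.
#' @return A data frame with columns `protocol`, `interval_ms`, `percent`.
#' @export
triplet_prediction <- function(params, kernels = kernel_params(),
                               intervals = c(5, 10), repetitions = 10,
                               frequency_hz = 1, dt = 0.1, w_init = 0.5) {
  validate_params(params)
  protos <- list("pre-post"      = c("E", "B"),
                 "post-pre"      = c("B", "E"),
                 "pre-post-pre"  = c("E", "B", "E"),
                 "post-pre-post" = c("B", "E", "B"))
  period <- 1000 / frequency_hz
  tail_tau <- max(kernels$epsp_tau_decay, kernels$adp_tau, 10)
  out <- expand.grid(protocol = names(protos), interval_ms = intervals,
                     stringsAsFactors = FALSE)
  out$percent <- NA_real_
  for (r in seq_len(nrow(out))) {
    patt <- protos[[out$protocol[r]]]
    off <- (seq_along(patt) - 1L) * out$interval_ms[r]
    if (period < max(off))
      stop("repetition period shorter than the spike pattern")
    base <- 50 + (seq_len(repetitions) - 1L) * period
    dur <- max(base) + max(off) + 5 * tail_tau + 50
    n <- floor(dur / dt + 1e-9) + 1L
    t <- (seq_len(n) - 1L) * dt
    v <- numeric(n)
    pre_t <- numeric(0)
    for (j in seq_along(patt)) {
      ev <- base + off[j]
      if (patt[j] == "E") {
        pre_t <- c(pre_t, ev)
        for (e in ev) v <- v + .epsp_wave(t - e, kernels)
      } else {
        for (e in ev) v <- v + .bap_wave(t - e, kernels)
      }
    }
    sim <- vbp_simulate(voltage_trace(v, dt = dt), spike_train(sort(pre_t)),
                        params, w_init = w_init)
    out$percent[r] <- 100 * (1 + sim$relative_change)
  }
  out
}
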