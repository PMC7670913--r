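# Least-squares objective and bounded multi-start fitting.

#' Squared-error objective between predicted and measured weight changes
#'
#' `SE = sum_pp (dw_pred_pp - dw_exp_pp)^2`, with both sides expressed as
#' fractions of the initial weight.
#'
#' @param predicted,experimental numeric vectors of equal length (>= 1) of
#'   relative weight changes.
#' @return The sum of squared differences.
#' @export
compute_se <- function(predicted, experimental) {
  if (length(predicted) != length(experimental) || !length(predicted))
    stop("predicted and experimental must have equal positive length")
  sum((predicted - experimental)^2)
}

#' Normalized fitting error
#'
#' The squared error divided by the number of protocol outcomes, making
#' errors comparable across datasets of different size.
#'
#' @param se squared error as from [compute_se()].
#' @param n_protocols number of protocol outcomes (>= 1).
#' @return `se / n_protocols`.
#' @export
normalized_error <- function(se, n_protocols) {
  if (n_protocols < 1) stop("n_protocols must be >= 1")
  se / n_protocols
}

#' Deterministic stratified initial points for the multi-start search
#'
#' Draws a seeded Latin-hypercube sample of parameter vectors strictly
#' inside the bounds.  The two amplitudes are stratified on a log scale
#' (their bounds span three decades); every point is repaired to satisfy
#' `theta_plus > theta_0`.  Identical `(bounds, n, seed)` give identical
#' output; the global RNG state is untouched.
#'
#' @param bounds a 9 x 2 bounds matrix as from [default_param_bounds()].
#' @param n number of points (default 25).
#' @param seed integer seed.
#' @return A list of `n` [plasticity_params()] objects.
#' @export
generate_initial_points <- function(bounds = default_param_bounds(), n = 25,
                                    seed = 1) {
  stopifnot(n >= 1)
  bounds <- check_bounds(bounds)
  u <- with_seed(seed, lhs::randomLHS(n, 9L))
  colnames(u) <- .PAR_NAMES
  # keep points strictly inside the box
  u <- 0.02 + 0.96 * u
  pts <- matrix(NA_real_, n, 9L, dimnames = list(NULL, .PAR_NAMES))
  for (nm in .PAR_NAMES) {
    lo <- bounds[nm, 1L]; hi <- bounds[nm, 2L]
    if (nm %in% c("A_LTP", "A_LTD")) {
      pts[, nm] <- 10^(log10(lo) + u[, nm] * (log10(hi) - log10(lo)))
    } else if (nm == "b_theta") {
      # sqrt-scale stratification: spreads starts across veto regimes instead
      # of piling them into the saturated high-b_theta plateau
      pts[, nm] <- (sqrt(lo) + u[, nm] * (sqrt(hi) - sqrt(lo)))^2
    } else {
      pts[, nm] <- lo + u[, nm] * (hi - lo)
    }
  }
  # repair the ordering constraint; theta_plus >= 8.5 keeps this in bounds
  bad <- pts[, "theta_0"] >= pts[, "theta_plus"] - 0.5
  pts[bad, "theta_0"] <- pmax(bounds["theta_0", 1L],
                              pts[bad, "theta_plus"] - 0.5)
  lapply(seq_len(n), function(i) as_plasticity_params(pts[i, ]))
}

# ---- internal parameter transform (A's on log10 scale) ---------------------

.to_tpar <- function(p) {
  t <- as.numeric(p[.PAR_NAMES]); names(t) <- .PAR_NAMES
  t[c("A_LTP", "A_LTD")] <- log10(t[c("A_LTP", "A_LTD")])
  t
}

.from_tpar <- function(t) {
  p <- t
  p[c("A_LTP", "A_LTD")] <- 10^(t[c("A_LTP", "A_LTD")])
  p
}

# precompute per-component step-end voltage samples and spike counts
.cache_dataset <- function(data) {
  lapply(data, function(r) {
    lapply(r$components, function(cc) {
      tr <- as_voltage_trace(cc$trace)
      sp <- as_spike_train(cc$spikes)
      n_steps <- length(tr$values) - 1L
      list(values = tr$values[-1L], dt = tr$dt,
           counts = bin_spikes(sp$times, tr$t0, tr$dt, n_steps),
           reps = if (is.null(cc$reps)) 1 else cc$reps)
    })
  })
}

.predict_cached <- function(p, cache, w_init) {
  vapply(cache, function(comps) {
    d <- 0
    for (cc in comps) {
      s <- .sim_core(cc$values, cc$dt, cc$counts, p, w_init = w_init)
      d <- d + cc$reps * (s$w_ltp - s$w_ltd)
    }
    d / w_init
  }, numeric(1))
}

#' Fit the plasticity rule to a set of protocol outcomes
#'
#' Minimizes the squared error between model-predicted and measured relative
#' weight changes over the nine rule parameters, subject to box bounds and
#' the ordering constraint `theta_plus > theta_0`.  A bounded
#' Levenberg--Marquardt local search ([minpack.lm::nls.lm()], amplitudes on a
#' log10 scale, ordering enforced by a penalty residual with post-run
#' repair) is run from `n_starts` seeded Latin-hypercube initial points plus
#' any `extra_starts`; the run with the smallest squared error wins.  The
#' whole procedure is deterministic given `(data, bounds, n_starts, seed)`.
#'
#' @param data a [vbp_dataset()] of protocol outcomes.
#' @param bounds 9 x 2 bounds matrix, see [default_param_bounds()].
#' @param n_starts number of stratified initial points (default 25).
#' @param seed integer seed for the initial-point design.
#' @param w_init initial synaptic weight used in all simulations.
#' @param fixed optional named numeric vector of parameters to hold fixed
#'   (e.g. `c(b_theta = 0, tau_theta = 10)` for a veto-free fit).
#' @param extra_starts optional list of additional [plasticity_params()]
#'   starting points.
#' @param maxiter maximum Levenberg--Marquardt iterations per start.
#' @param polish_top number of best first-stage runs to re-polish with
#'   `polish_maxiter` iterations (0 disables the polish stage).
#' @param polish_maxiter iteration budget of the polish stage.
#' @param screen_factor when > 1, a stratified sample of
#'   `screen_factor * n_starts` candidate points is evaluated once and only
#'   the best `n_starts` of them are refined by the local search (a
#'   deterministic scatter-search start selection; set to 1 to refine the
#'   raw stratified sample directly).
#' @param hop_rounds number of basin-hopping rounds after the multi-start
#'   stage: each round perturbs the incumbent best parameters
#'   multiplicatively by up to `hop_factor` (deterministically, from the
#'   seed), refines locally, and keeps the result if it improves.  `0`
#'   disables hopping.
#' @param hop_factor maximal multiplicative perturbation per parameter in a
#'   hop round.
#' @return An object of class `"vbp_fit"` with components `params` (best
#'   parameters), `lse` (its squared error), `per_protocol` (data frame of
#'   predicted and observed changes), `all_runs` (per-start squared errors),
#'   `start_index`, `n_protocols`, `bounds`, `fixed`, `data`, `call`.
#' @seealso [coef.vbp_fit()], [predict.vbp_fit()], [residuals.vbp_fit()],
#'   [plot.vbp_fit()], [simulate.vbp_fit()], [loo_crossval()],
#'   [veto_ablation()], [sensitivity_analysis()].
#' @export
vbp_fit <- function(data, bounds = default_param_bounds(), n_starts = 25,
                    seed = 1, w_init = 0.5, fixed = NULL,
                    extra_starts = list(), maxiter = 60, polish_top = 3,
                    polish_maxiter = 4 * maxiter, screen_factor = 8,
                    hop_rounds = 0, hop_factor = 2.5) {
  if (!inherits(data, "vbp_dataset")) stop("data must be a vbp_dataset")
  bounds <- check_bounds(bounds)
  cache <- .cache_dataset(data)
  obs <- vapply(data, `[[`, numeric(1), "dw_exp")
  ids <- vapply(data, `[[`, character(1), "id")

  fixed_names <- character(0)
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% .PAR_NAMES))
      stop("fixed must be a named vector of parameter values")
    fixed_names <- names(fixed)
  }
  free_names <- setdiff(.PAR_NAMES, fixed_names)
  if (!length(free_names)) stop("at least one parameter must be free")

  tlo <- .to_tpar(stats::setNames(bounds[, 1L], .PAR_NAMES))
  thi <- .to_tpar(stats::setNames(bounds[, 2L], .PAR_NAMES))
  # log10(0) guard for a zero lower bound on b_theta: b_theta stays raw, so
  # only the amplitude rows are transformed and those bounds are positive.

  assemble <- function(tfree) {
    t_all <- stats::setNames(numeric(9L), .PAR_NAMES)
    t_all[free_names] <- tfree
    p <- .from_tpar(t_all)
    if (length(fixed_names)) p[fixed_names] <- as.numeric(fixed[fixed_names])
    p
  }

  repair <- function(p) {
    p <- pmin(pmax(p, bounds[, 1L]), bounds[, 2L])
    if (p[["theta_0"]] >= p[["theta_plus"]])
      p[["theta_0"]] <- max(bounds["theta_0", 1L], p[["theta_plus"]] - 1e-3)
    p
  }

  residual_fn <- function(tfree) {
    p <- assemble(tfree)
    pen <- 10 * max(p[["theta_0"]] + 1e-3 - p[["theta_plus"]], 0)
    p <- repair(p)
    c(.predict_cached(p, cache, w_init) - obs, pen)
  }

  screen_factor <- max(1, round(screen_factor))
  starts <- generate_initial_points(bounds, n = n_starts * screen_factor,
                                    seed = seed)
  if (screen_factor > 1) {
    se0 <- vapply(starts, function(s) {
      p <- stats::setNames(as.numeric(s[.PAR_NAMES]), .PAR_NAMES)
      if (length(fixed_names)) p[fixed_names] <- as.numeric(fixed[fixed_names])
      p <- repair(p)
      compute_se(.predict_cached(p, cache, w_init), obs)
    }, numeric(1))
    starts <- starts[utils::head(order(se0), n_starts)]
  }
  starts <- c(starts, lapply(extra_starts, function(s) {
    validate_params(s)
    as_plasticity_params(repair(as.numeric(s[.PAR_NAMES]) |>
                                  stats::setNames(.PAR_NAMES)))
  }))

  run_one <- function(p_start, iters) {
    t0 <- .to_tpar(p_start)[free_names]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = t0, lower = tlo[free_names],
                         upper = thi[free_names], fn = residual_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = iters, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(list(se = Inf, params = NULL, failed = TRUE,
                  message = conditionMessage(fit)))
    p <- repair(assemble(fit$par))
    se <- compute_se(.predict_cached(p, cache, w_init), obs)
    list(se = se, params = p, failed = FALSE)
  }

  runs <- lapply(starts, function(s)
    run_one(stats::setNames(as.numeric(s[.PAR_NAMES]), .PAR_NAMES), maxiter))
  all_se <- vapply(runs, `[[`, numeric(1), "se")
  # polish the most promising basins with a larger iteration budget
  if (polish_top > 0) {
    for (i in utils::head(order(all_se), polish_top)) {
      if (!is.finite(all_se[i])) next
      ref <- run_one(runs[[i]]$params, polish_maxiter)
      if (!ref$failed && ref$se < runs[[i]]$se) runs[[i]] <- ref
    }
    all_se <- vapply(runs, `[[`, numeric(1), "se")
  }
  # basin hopping around the incumbent best
  if (hop_rounds > 0 && any(is.finite(all_se))) {
    ib <- which.min(all_se)
    fac <- with_seed(seed + 1000L,
                     matrix(exp(stats::runif(9L * hop_rounds,
                                             -log(hop_factor),
                                             log(hop_factor))),
                            hop_rounds, 9L, byrow = TRUE))
    for (r in seq_len(hop_rounds)) {
      # every third hop is wide, to escape deeper decoy basins
      f_r <- if (r %% 3L == 0L) fac[r, ]^2 else fac[r, ]
      p0 <- runs[[ib]]$params * f_r
      p0 <- repair(stats::setNames(pmin(pmax(p0, bounds[, 1L]),
                                        bounds[, 2L]), .PAR_NAMES))
      hop <- run_one(p0, maxiter)
      if (!hop$failed && hop$se < runs[[ib]]$se) {
        runs[[ib]] <- hop
        if (hop$se < 1e-10) break
      }
    }
    ref <- run_one(runs[[ib]]$params, polish_maxiter)
    if (!ref$failed && ref$se < runs[[ib]]$se) runs[[ib]] <- ref
    all_se <- vapply(runs, `[[`, numeric(1), "se")
  }
  if (all(!is.finite(all_se)))
    stop("all optimization starts failed")
  best <- which.min(all_se)
  p_best <- as_plasticity_params(runs[[best]]$params)
  pred <- .predict_cached(p_best, cache, w_init)

  structure(list(
    params = p_best,
    lse = all_se[best],
    per_protocol = data.frame(id = ids, predicted = pred, observed = obs,
                              residual = obs - pred),
    all_runs = all_se,
    start_index = best,
    n_protocols = length(obs),
    bounds = bounds,
    fixed = fixed,
    w_init = w_init,
    data = data,
    call = match.call()), class = "vbp_fit")
}

# ---- methods ---------------------------------------------------------------

#' @export
print.vbp_fit <- function(x, digits = 4L, ...) {
  cat("Voltage-based plasticity rule fit\n")
  cat(sprintf("  %d protocol outcomes, %d optimization starts\n",
              x$n_protocols, length(x$all_runs)))
  cat(sprintf("  least squared error: %.4g (normalized: %.4g)\n",
              x$lse, normalized_error(x$lse, x$n_protocols)))
  if (!is.null(x$fixed))
    cat("  fixed:", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n")
  cat("Parameters:\n")
  print(format(data.frame(value = as.numeric(x$params),
                          row.names = names(x$params)), digits = digits))
  invisible(x)
}

#' @export
summary.vbp_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.vbp_fit")
}

#' @export
print.summary.vbp_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-protocol outcomes (fractions of initial weight):\n")
  print(x$fit$per_protocol, row.names = FALSE, digits = 4L)
  ok <- sum(is.finite(x$fit$all_runs))
  cat(sprintf("\nStarts converged: %d/%d; winning start: %d; SE spread: [%.3g, %.3g]\n",
              ok, length(x$fit$all_runs), x$fit$start_index,
              min(x$fit$all_runs), max(x$fit$all_runs[is.finite(x$fit$all_runs)])))
  invisible(x)
}

#' Extract fitted parameters
#' @param object a `vbp_fit`.
#' @param ... unused.
#' @return Named numeric vector of the nine parameters.
#' @export
coef.vbp_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$params), names(object$params))
}

#' Predict relative weight changes from a fitted rule
#' @param object a `vbp_fit`.
#' @param newdata a [vbp_dataset()]; default the training data.
#' @param ... unused.
#' @return Numeric vector of predicted relative weight changes (fractions),
#'   named by protocol id.
#' @export
predict.vbp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    stats::setNames(object$per_protocol$predicted, object$per_protocol$id)
  } else {
    if (inherits(newdata, "protocol_record")) newdata <- vbp_dataset(list(newdata))
    stats::setNames(predict_dw(object$params, newdata, w_init = object$w_init),
                    vapply(newdata, `[[`, character(1), "id"))
  }
}

#' @export
fitted.vbp_fit <- function(object, ...) {
  stats::setNames(object$per_protocol$predicted, object$per_protocol$id)
}

#' @export
residuals.vbp_fit <- function(object, ...) {
  stats::setNames(object$per_protocol$residual, object$per_protocol$id)
}

#' Observed versus predicted weight changes
#' @param x a `vbp_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vbp_fit <- function(x, ...) {
  pp <- x$per_protocol
  rng <- range(c(pp$predicted, pp$observed, 0))
  graphics::plot(pp$predicted, pp$observed, xlim = rng, ylim = rng,
                 xlab = expression(predicted ~ Delta * w / w[i]),
                 ylab = expression(observed ~ Delta * w / w[i]),
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::abline(h = 0, v = 0, col = "grey85")
  invisible(x)
}

#' Simulate synthetic datasets from a fitted rule
#'
#' Draws `nsim` datasets whose outcomes are the fitted model's predictions on
#' the training protocols plus Gaussian noise.
#'
#' @param object a `vbp_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param noise_sd outcome noise sd; defaults to the residual sd of the fit.
#' @param ... unused.
#' @return A list of `nsim` [vbp_dataset()]s.
#' @export
simulate.vbp_fit <- function(object, nsim = 1, seed = 1, noise_sd = NULL, ...) {
  if (is.null(noise_sd)) {
    r <- object$per_protocol$residual
    noise_sd <- if (length(r) > 1L) stats::sd(r) else 0
  }
  pred <- object$per_protocol$predicted
  ids <- object$per_protocol$id
  lapply(seq_len(nsim), function(k) {
    noise <- with_seed(seed + k - 1L, stats::rnorm(length(pred), 0, noise_sd))
    vbp_dataset(lapply(seq_along(pred), function(i)
      protocol_record(ids[i], object$data[[i]]$components, pred[i] + noise[i])))
  })
}
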