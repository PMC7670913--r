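# Parameter container and published parameter sets for the plasticity rule.

# canonical ordering used throughout the package
.PAR_NAMES <- c("tau_x", "tau_plus", "tau_minus", "theta_plus", "theta_0",
                "A_LTP", "A_LTD", "b_theta", "tau_theta")

#' Parameters of the voltage-based plasticity rule
#'
#' Bundles the nine parameters of the rule into a validated named numeric
#' vector of class `"vbp_params"`.  The rule couples a presynaptic glutamate
#' trace `x_bar` (decay `tau_x`) with two low-pass-filtered copies of the
#' dendritic voltage: `u_bar_plus` (time constant `tau_plus`, compared against
#' the potentiation threshold `theta_plus`) drives LTP with amplitude `A_LTP`,
#' and `u_bar_minus` (time constant `tau_minus`, compared against the
#' depression threshold `theta_0 + theta(t)`) drives LTD with amplitude
#' `A_LTD`.  Ongoing potentiation transiently raises the LTD threshold by
#' `b_theta` times the LTP rate, relaxing with time constant `tau_theta`
#' (the "veto" of LTP on LTD).
#'
#' @param tau_x presynaptic trace decay time constant (ms).
#' @param tau_plus time constant of the LTP voltage filter (ms).
#' @param tau_minus time constant of the LTD voltage filter (ms).
#' @param theta_plus LTP voltage threshold (mV above rest).
#' @param theta_0 fixed part of the LTD voltage threshold (mV above rest);
#'   must be strictly below `theta_plus`.
#' @param A_LTP potentiation amplitude (1/(mV*ms)).
#' @param A_LTD depression amplitude (1/(mV*ms)).
#' @param b_theta veto interaction strength (mV*ms); `0` disables the veto.
#' @param tau_theta veto decay time constant (ms).
#'
#' @return A named numeric vector of class `"vbp_params"`.
#' @seealso [vbp_preset_params()] for published parameter sets,
#'   [default_param_bounds()] for the box used during fitting.
#' @export
#' @examples
#' p <- plasticity_params(tau_x = 5, tau_plus = 6, tau_minus = 15,
#'                        theta_plus = 10, theta_0 = 5,
#'                        A_LTP = 1e-4, A_LTD = 1e-4,
#'                        b_theta = 31000, tau_theta = 14)
#' p
plasticity_params <- function(tau_x, tau_plus, tau_minus, theta_plus, theta_0,
                              A_LTP, A_LTD, b_theta, tau_theta) {
  p <- c(tau_x = tau_x, tau_plus = tau_plus, tau_minus = tau_minus,
         theta_plus = theta_plus, theta_0 = theta_0,
         A_LTP = A_LTP, A_LTD = A_LTD,
         b_theta = b_theta, tau_theta = tau_theta)
  validate_params(p)
  structure(p, class = "vbp_params")
}

#' @rdname plasticity_params
#' @param x a named numeric vector (any order) holding all nine parameters.
#' @export
as_plasticity_params <- function(x) {
  if (is.null(names(x)) || !all(.PAR_NAMES %in% names(x)))
    stop("need all nine named parameters: ", paste(.PAR_NAMES, collapse = ", "))
  do.call(plasticity_params, as.list(as.numeric(x[.PAR_NAMES]) |>
                                       stats::setNames(.PAR_NAMES)))
}

validate_params <- function(p) {
  stopifnot(is.numeric(p), length(p) == 9L)
  if (!all(is.finite(p)))
    stop("all plasticity parameters must be finite")
  pos <- setdiff(.PAR_NAMES, "b_theta")
  bad <- pos[p[pos] <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  if (p[["b_theta"]] < 0)
    stop("b_theta must be >= 0")
  if (p[["theta_plus"]] <= p[["theta_0"]])
    stop("theta_plus must exceed theta_0 (got theta_plus = ",
         p[["theta_plus"]], ", theta_0 = ", p[["theta_0"]], ")")
  invisible(p)
}

#' @export
print.vbp_params <- function(x, ...) {
  cat("Voltage-based plasticity parameters\n")
  df <- data.frame(value = as.numeric(x), row.names = names(x))
  print(format(df, digits = 4L), ...)
  invisible(x)
}

#' Published parameter sets for the plasticity rule
#'
#' Returns one of the parameter sets that have been reported to account for
#' plasticity at specific synapse types, usable as realistic defaults and as
#' starting points for exploration:
#' \describe{
#'   \item{`"clamp-linear"`}{set giving an approximately linear
#'     voltage--plasticity relation under presynaptic stimulation paired with
#'     constant somatic voltage clamp.}
#'   \item{`"clamp-nonlinear"`}{companion set giving a non-linear
#'     voltage--plasticity relation under the same clamp protocol.}
#'   \item{`"ca3-subthreshold"`}{hippocampal CA3 recurrent synapses probed
#'     with subthreshold and burst-STDP protocols.}
#'   \item{`"l23-l5-distal"`}{neocortical synapses between layer 2/3 and
#'     layer 5 pyramidal neurons (distance-dependent burst STDP).}
#'   \item{`"l5-l5"`}{neocortical L5--L5 connections (frequency-dependent
#'     STDP, basal dendrites).}
#' }
#'
#' @param name one of the preset names above.
#' @return A [plasticity_params()] object.
#' @export
vbp_preset_params <- function(name = c("clamp-linear", "clamp-nonlinear",
                                       "ca3-subthreshold", "l23-l5-distal",
                                       "l5-l5")) {
  name <- match.arg(name)
  switch(name,
    "clamp-linear" = plasticity_params(
      tau_x = 5, tau_plus = 6, tau_minus = 15, theta_plus = 10, theta_0 = 5,
      A_LTP = 1e-4, A_LTD = 1e-4, b_theta = 31000, tau_theta = 14),
    "clamp-nonlinear" = plasticity_params(
      tau_x = 5, tau_plus = 7, tau_minus = 15, theta_plus = 13, theta_0 = 7,
      A_LTP = 1e-4, A_LTD = 1e-4, b_theta = 45000, tau_theta = 5),
    "ca3-subthreshold" = plasticity_params(
      tau_x = 14.3, tau_plus = 7.80, tau_minus = 53.3,
      theta_plus = 9.94, theta_0 = 4.04,
      A_LTP = 225e-5, A_LTD = 691e-5, b_theta = 9.91e-1, tau_theta = 1.99),
    "l23-l5-distal" = plasticity_params(
      tau_x = 22.4, tau_plus = 2.00, tau_minus = 60.0,
      theta_plus = 27.1, theta_0 = 6.20,
      A_LTP = 4.27e-5, A_LTD = 16.5e-5, b_theta = 1.00e4, tau_theta = 29.1),
    "l5-l5" = plasticity_params(
      tau_x = 5.08, tau_plus = 17.8, tau_minus = 24.9,
      theta_plus = 11.8, theta_0 = 6.50,
      A_LTP = 37.2e-5, A_LTD = 31.2e-5, b_theta = 24.7e4, tau_theta = 2.49))
}

#' Default parameter box used during fitting
#'
#' Lower and upper bounds for the nine parameters of the rule, as used by the
#' bounded multi-start least-squares search in [vbp_fit()].  Time constants
#' are bounded below at 2 ms (1 ms for the veto decay) and above below 100 ms;
#' the amplitudes span three decades.
#'
#' @return A 9 x 2 numeric matrix with rownames equal to the parameter names
#'   and columns `lower`, `upper`.
#' @export
default_param_bounds <- function() {
  m <- rbind(tau_x      = c(2,     30),
             tau_plus   = c(2,     60),
             tau_minus  = c(2,     60),
             theta_plus = c(8.5,   30),
             theta_0    = c(2.5,   15),
             A_LTP      = c(1e-5,  1e-2),
             A_LTD      = c(1e-5,  1e-2),
             b_theta    = c(0,     5e5),
             tau_theta  = c(1,     100))
  colnames(m) <- c("lower", "upper")
  m
}

check_bounds <- function(bounds) {
  if (!is.matrix(bounds) || nrow(bounds) != 9L || ncol(bounds) != 2L ||
      is.null(rownames(bounds)) || !setequal(rownames(bounds), .PAR_NAMES))
    stop("bounds must be a 9 x 2 matrix with the parameter names as rownames")
  bounds <- bounds[.PAR_NAMES, , drop = FALSE]
  if (any(bounds[, 1L] >= bounds[, 2L]))
    stop("each lower bound must be strictly below its upper bound")
  bounds
}
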