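#' Network and neuron parameters
#'
#' Bundles all scalar parameters of a sparse random network of leaky
#' integrate-and-fire (LIF) neurons with delayed delta synapses.  Time is
#' measured in units where the membrane time constant is \code{1/gamma};
#' potentials in units of the firing threshold (\code{V_theta = 1},
#' \code{V_reset = 0} by convention).
#'
#' The constant external drive must be supra-threshold
#' (\code{I_ext > gamma * V_theta}) so that every neuron fires periodically on
#' its own and irregular background spiking arises from the recurrent input,
#' not from noise in the drive.
#'
#' @param N neuron count (integer >= 2).
#' @param p_conn probability that any ordered pair of distinct neurons is
#'   connected, in (0, 1].
#' @param p_exc,p_inh probability that a realized connection is excitatory /
#'   inhibitory; must sum to 1.
#' @param eps_exc excitatory coupling strength (potential units, > 0).
#' @param eps_inh inhibitory coupling strength (potential units, <= 0).
#' @param gamma inverse membrane time constant (1/time, > 0).
#' @param I_ext constant external drive (potential/time), must exceed
#'   \code{gamma * V_theta}.
#' @param V_theta firing threshold (potential). Fixed at 1 by convention.
#' @param V_reset reset potential (potential). Fixed at 0 by convention.
#' @param tau synaptic transmission delay (time, > 0).
#' @return an object of class \code{"model_params"}.
#' @examples
#' p <- model_params(N = 1000, p_conn = 0.1, p_exc = 0.8, eps_exc = 0.01,
#'                   eps_inh = -0.04, I_ext = 1.3)
#' p
#' @export
model_params <- function(N, p_conn, p_exc, eps_exc, eps_inh,
                         I_ext, gamma = 1, tau = 0.1,
                         p_inh = 1 - p_exc, V_theta = 1, V_reset = 0) {
  N <- as.integer(N)
  stopifnot(N >= 2, p_conn > 0, p_conn <= 1,
            p_exc >= 0, p_exc <= 1, p_inh >= 0, p_inh <= 1,
            eps_exc > 0, eps_inh <= 0, gamma > 0, tau > 0,
            V_reset < V_theta)
  if (abs(p_exc + p_inh - 1) > 1e-12)
    stop("p_exc + p_inh must equal 1 (each connection is exactly one sign)")
  if (I_ext <= gamma * V_theta)
    stop("supra-threshold drive required: I_ext must exceed gamma * V_theta")
  structure(list(N = N, p_conn = p_conn, p_exc = p_exc, p_inh = p_inh,
                 eps_exc = eps_exc, eps_inh = eps_inh, gamma = gamma,
                 I_ext = I_ext, V_theta = V_theta, V_reset = V_reset,
                 tau = tau),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("LIF network parameters\n")
  cat(sprintf("  N = %d, p_conn = %g  (mean in-degree %.1f)\n",
              x$N, x$p_conn, x$p_conn * (x$N - 1)))
  cat(sprintf("  p_exc = %g, p_inh = %g, eps_exc = %g, eps_inh = %g\n",
              x$p_exc, x$p_inh, x$eps_exc, x$eps_inh))
  cat(sprintf("  gamma = %g, I_ext = %g, V_theta = %g, V_reset = %g, tau = %g\n",
              x$gamma, x$I_ext, x$V_theta, x$V_reset, x$tau))
  tot <- mean_total_input_strengths(x)
  cat(sprintf("  mean total input strengths: E_tot = %g, I_tot = %g\n",
              tot[["E_tot"]], tot[["I_tot"]]))
  invisible(x)
}

#' Dendritic modulation function
#'
#' The piecewise-linear sigmoid that maps the peak EPSP amplitude expected
#' from linearly adding the strengths of synchronously received excitatory
#' inputs to the actual somatic depolarization.  It is the identity below
#' \code{theta_b} (no dendritic spike), affine between \code{theta_b} and
#' \code{theta_s} (supra-additive amplification by a fast dendritic sodium
#' spike), and constant at \code{s_sat} beyond \code{theta_s} (saturation).
#' Inhibitory inputs never pass through this function; they sum linearly.
#'
#' @param theta_b onset of supra-additivity (potential units, > 0).
#' @param theta_s onset of saturation (potential units, >= theta_b).
#' @param s_sat saturation level (potential units, >= theta_b).
#' @param linear if \code{TRUE} the modulation is the identity for all inputs
#'   (the conventional, additively coupled network).
#' @return an object of class \code{"dendritic_modulation"}.
#' @examples
#' m <- dendritic_modulation(theta_b = 2, theta_s = 4, s_sat = 6)
#' sigma_modulate(c(1, 3, 9), m)   # identity, interpolation, saturation
#' @export
dendritic_modulation <- function(theta_b = NULL, theta_s = NULL, s_sat = NULL,
                                 linear = FALSE) {
  if (linear) {
    return(structure(list(theta_b = Inf, theta_s = Inf, s_sat = Inf,
                          linear = TRUE),
                     class = "dendritic_modulation"))
  }
  stopifnot(is.numeric(theta_b), is.numeric(theta_s), is.numeric(s_sat),
            theta_b > 0, theta_s >= theta_b, s_sat >= theta_b)
  structure(list(theta_b = theta_b, theta_s = theta_s, s_sat = s_sat,
                 linear = FALSE),
            class = "dendritic_modulation")
}

#' @export
print.dendritic_modulation <- function(x, ...) {
  if (x$linear) {
    cat("Dendritic modulation: linear (identity, no supra-additivity)\n")
  } else {
    cat(sprintf(
      "Dendritic modulation: identity below %g, saturates at %g beyond %g\n",
      x$theta_b, x$s_sat, x$theta_s))
  }
  invisible(x)
}

#' Apply the dendritic modulation to a summed excitatory input
#'
#' @param x summed expected EPSP amplitude(s), must be >= 0 (inhibition is
#'   never passed through the modulation).
#' @param mod a \code{\link{dendritic_modulation}}.
#' @return the actual EPSP amplitude(s), same length as \code{x}.
#' @export
sigma_modulate <- function(x, mod) {
  stopifnot(inherits(mod, "dendritic_modulation"))
  if (any(x < 0)) stop("sigma_modulate: negative input (inhibition must not pass through the modulation)")
  if (mod$linear) return(x)
  b <- mod$theta_b; s <- mod$theta_s; sat <- mod$s_sat
  out <- x
  if (s > b) {
    mid <- x > b & x < s
    out[mid] <- b + (sat - b) * (x[mid] - b) / (s - b)
  }
  out[x >= s] <- sat
  out
}

#' Mean total input strengths
#'
#' The expected summed excitatory and inhibitory coupling received by one
#' neuron from the whole network, \code{E_tot = N * p_conn * p_exc * eps_exc}
#' and \code{I_tot = N * p_conn * p_inh * eps_inh} (signed).  These are the
#' natural axes for coupling-strength parameter scans.
#'
#' @param params a \code{\link{model_params}}.
#' @return named numeric vector \code{c(E_tot=, I_tot=)}.
#' @seealso \code{\link{strengths_from_totals}} for the inverse mapping.
#' @export
mean_total_input_strengths <- function(params) {
  stopifnot(inherits(params, "model_params"))
  c(E_tot = params$N * params$p_conn * params$p_exc * params$eps_exc,
    I_tot = params$N * params$p_conn * params$p_inh * params$eps_inh)
}

#' Coupling strengths from target mean total input strengths
#'
#' Inverse of \code{\link{mean_total_input_strengths}} at fixed topology
#' statistics: returns a copy of \code{params} whose \code{eps_exc},
#' \code{eps_inh} realize the requested totals.
#'
#' @param params a \code{\link{model_params}} supplying N, p_conn, p_exc.
#' @param E_tot target mean total excitatory input strength (> 0).
#' @param I_tot target mean total inhibitory input strength (<= 0).
#' @return a \code{\link{model_params}} with rescaled coupling strengths.
#' @export
strengths_from_totals <- function(params, E_tot, I_tot) {
  stopifnot(inherits(params, "model_params"), E_tot > 0, I_tot <= 0)
  params$eps_exc <- E_tot / (params$N * params$p_conn * params$p_exc)
  params$eps_inh <- if (params$p_inh > 0)
    I_tot / (params$N * params$p_conn * params$p_inh) else 0
  params
}
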