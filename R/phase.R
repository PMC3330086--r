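#' Phase representation of the LIF neuron
#'
#' Between events the LIF membrane potential obeys
#' \code{dV/dt = -gamma V + I_ext}; the phase \code{phi} is the time since the
#' last reset under free evolution, so that the potential is recovered by the
#' transfer function
#' \deqn{U(\phi) = I/\gamma + (V_r - I/\gamma) e^{-\gamma\phi},}
#' which is strictly increasing and concave.  The phase advances with unit
#' slope between events, which makes the event-driven simulation exact.
#' \code{U_inv} is the closed-form inverse, defined for all
#' \code{V < I_ext/gamma} (including potentials below reset, which map to
#' negative phases).
#'
#' @param params a \code{\link{model_params}}.
#' @return an object of class \code{"phase_functions"} with elements
#'   \code{U}, \code{U_inv} (vectorized functions), \code{phi_theta} (phase
#'   threshold) and \code{T_free} (free inter-spike interval, equal to
#'   \code{phi_theta}).
#' @export
phase_functions <- function(params) {
  stopifnot(inherits(params, "model_params"))
  g <- params$gamma; I <- params$I_ext
  Vr <- params$V_reset; Vt <- params$V_theta
  Vinf <- I / g
  U <- function(phi) Vinf + (Vr - Vinf) * exp(-g * phi)
  U_inv <- function(V) {
    if (any(V >= Vinf)) stop("U_inv: potential at or above I_ext/gamma cannot be inverted")
    log((I - g * Vr) / (I - g * V)) / g
  }
  Tf <- free_period(params)
  structure(list(U = U, U_inv = U_inv, phi_theta = Tf, T_free = Tf,
                 params = params),
            class = "phase_functions")
}

#' Free inter-spike interval of the uncoupled LIF neuron
#'
#' Closed form \code{T_free = (1/gamma) log[(I - gamma V_reset) /
#' (I - gamma V_theta)]}, the time a neuron takes from reset to threshold
#' under the constant supra-threshold drive alone.  Equals the phase
#' threshold \code{phi_theta}.
#'
#' @param params a \code{\link{model_params}}.
#' @return the free period (time units).
#' @export
free_period <- function(params) {
  stopifnot(inherits(params, "model_params"))
  g <- params$gamma; I <- params$I_ext
  if (I <= g * params$V_theta)
    stop("free_period: drive is sub-threshold, the free period is infinite")
  log((I - g * params$V_reset) / (I - g * params$V_theta)) / g
}

#' Apply a synaptic input in phase representation
#'
#' The response function \code{H_lambda(phi) = U_inv(U(phi) + lambda)} of the
#' LIF neuron: a delta input of total strength \code{lambda} (signed; the
#' caller applies the dendritic modulation to the excitatory part first)
#' shifts the potential instantaneously.  If the shifted potential reaches or
#' exceeds threshold the neuron fires and is reset to \code{V_reset} exactly
#' (overshoot discarded); otherwise the new phase is returned, possibly
#' negative for potentials below reset.
#'
#' @param phi current phase(s), each \code{<= phi_theta}.
#' @param lam total input strength (signed potential), scalar or same length.
#' @param pf a \code{\link{phase_functions}}.
#' @return list with \code{phi_new} and logical \code{fired}, vectorized.
#' @export
apply_input <- function(phi, lam, pf) {
  stopifnot(inherits(pf, "phase_functions"))
  p <- pf$params
  V <- pf$U(phi) + lam
  fired <- V >= p$V_theta
  phi_new <- phi
  phi_new[fired] <- 0
  if (any(!fired)) {
    Vs <- V[!fired]
    # guard: potentials driven implausibly far below reset are clamped
    floor_V <- -(p$I_ext / p$gamma)
    if (any(Vs <= floor_V)) {
      warning("apply_input: potential clamped at -I_ext/gamma")
      Vs <- pmax(Vs, floor_V + 1e-12)
    }
    phi_new[!fired] <- pf$U_inv(Vs)
  }
  list(phi_new = phi_new, fired = fired)
}
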