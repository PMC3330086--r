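# Analytical background theory: diffusion approximation of the membrane
# potential distribution, self-consistent (Siegert) firing rate, excitation
# probability, and the binomial group-size transition model.

# scaled complementary error function exp(z^2) erfc(z), stable for all z
# that matter here (overflows only for z < -26, where the Siegert integrand
# is astronomically large and the rate is indistinguishable from zero).
erfcx_stable <- function(z) {
  out <- numeric(length(z))
  small <- abs(z) <= 25
  out[small] <- exp(z[small]^2) * 2 * stats::pnorm(-z[small] * sqrt(2))
  big <- z > 25
  if (any(big)) {
    zi <- z[big]
    out[big] <- (1 - 0.5 / zi^2 + 0.75 / zi^4) / (zi * sqrt(pi))
  }
  neg <- z < -25
  if (any(neg)) out[neg] <- Inf
  out
}

# effective single-spike excitatory strength: background spikes arrive almost
# always alone, so the dendritic modulation acts on one EPSP at a time
eff_exc <- function(params, mod) sigma_modulate(params$eps_exc, mod)

# drift (potential/time) and diffusion coefficient (potential^2/time) of the
# white-noise approximation to the Poissonian synaptic bombardment at
# background rate nu per neuron
diffusion_moments <- function(params, mod, nu) {
  Kp <- params$N * params$p_conn
  ee <- eff_exc(params, mod)
  mu <- params$I_ext + nu * Kp * (params$p_exc * ee +
                                    params$p_inh * params$eps_inh)
  D <- nu * Kp * (params$p_exc * ee^2 + params$p_inh * params$eps_inh^2)
  c(mu = mu, D = D)
}

# mean first-passage rate of the LIF neuron driven by white noise with drift
# mu and diffusion coefficient D (Siegert formula); exact noiseless limit.
siegert_rate <- function(params, mu, D) {
  g <- params$gamma
  if (D <= 0) {
    if (mu <= g * params$V_theta) return(0)
    return(g / log((mu - g * params$V_reset) / (mu - g * params$V_theta)))
  }
  mu_V <- mu / g
  sig <- sqrt(D / g)
  y_r <- (params$V_reset - mu_V) / sig
  y_t <- (params$V_theta - mu_V) / sig
  if (y_t > 26) return(0)  # deeply sub-threshold: rate below double precision
  Tisi <- sqrt(pi) / g *
    stats::integrate(function(u) erfcx_stable(-u), y_r, y_t,
                     rel.tol = 1e-10, abs.tol = 0)$value
  1 / Tisi
}

#' Self-consistent background firing rate
#'
#' Solves \eqn{\nu = \mathrm{Siegert}(\mu(\nu), \sigma_w^2(\nu))} where the
#' background activity is modelled as independent Poissonian spike trains:
#' drift \eqn{\mu(\nu) = I_{ext} + \nu N p (p_e \epsilon_e + p_i \epsilon_i)}
#' and diffusion \eqn{\sigma_w^2(\nu) = \nu N p (p_e \epsilon_e^2 + p_i
#' \epsilon_i^2)}.  With zero coupling the rate equals \code{1/free_period}
#' exactly.
#'
#' @param params a \code{\link{model_params}}.
#' @param mod a \code{\link{dendritic_modulation}} (single background spikes
#'   pass through its identity region; supplied for completeness).
#' @param rate_cap upper bracket for the root search (units 1/time).
#' @param tol relative tolerance of the fixed point.
#' @return the stationary per-neuron firing rate (1/time).
#' @export
self_consistent_rate <- function(params, mod = dendritic_modulation(linear = TRUE),
                                 rate_cap = NULL, tol = 1e-8) {
  stopifnot(inherits(params, "model_params"))
  nu0 <- 1 / free_period(params)
  if (params$eps_exc == 0 && params$eps_inh == 0) return(nu0)
  if (is.null(rate_cap)) rate_cap <- 50 * nu0
  h <- function(nu) {
    m <- diffusion_moments(params, mod, nu)
    siegert_rate(params, m[["mu"]], m[["D"]]) - nu
  }
  if (h(rate_cap) >= 0)
    stop(sprintf("self_consistent_rate: no root in [0, %g]; raise rate_cap",
                 rate_cap))
  r <- stats::uniroot(h, c(0, rate_cap), tol = tol * nu0)
  r$root
}

new_stationary_density <- function(grid, density, rate_nu, source, params) {
  dx <- diff(grid)
  Z <- sum(dx * (density[-1] + density[-length(density)]) / 2)
  density <- density / Z
  cum <- c(0, cumsum(dx * (density[-1] + density[-length(density)]) / 2))
  # right cumulative: F_right(V) = integral from V to V_theta
  Fright <- stats::approxfun(grid, cum[length(cum)] - cum, rule = 2)
  structure(list(grid = grid, density = density, rate_nu = rate_nu,
                 source = source, V_theta = params$V_theta,
                 V_low = grid[1], Fright = Fright),
            class = "stationary_density")
}

#' @export
print.stationary_density <- function(x, ...) {
  cat(sprintf(
    "Stationary membrane-potential density (%s): %d grid points on [%.3g, %.3g], rate nu = %.4g\n",
    x$source, length(x$grid), x$grid[1], x$V_theta, x$rate_nu))
  invisible(x)
}

#' @export
plot.stationary_density <- function(x, ...) {
  plot(x$grid, x$density, type = "l", xlab = "membrane potential V",
       ylab = "P(V)", ...)
  invisible(x)
}

#' Stationary membrane-potential density in diffusion approximation
#'
#' Standard stationary Fokker--Planck solution for the leaky
#' integrate-and-fire neuron driven by white noise with mean
#' \eqn{\mu(\nu)} and variance \eqn{\sigma_w^2(\nu)} (from
#' \code{\link{self_consistent_rate}}'s moment closure), with an absorbing
#' boundary at \code{V_theta} and probability re-injection at
#' \code{V_reset}:
#' \deqn{P(V) \propto e^{-\gamma (V-\mu_V)^2/\sigma_w^2}
#'   \int_{\max(V, V_r)}^{V_\theta} e^{\gamma (u-\mu_V)^2/\sigma_w^2} du.}
#' The integral is evaluated by a numerically stable upward recursion on the
#' output grid (all exponents kept non-positive in the mean-driven regime)
#' and the result normalized by trapezoidal quadrature.  For
#' \eqn{\sigma_w = 0} the deterministic-flow occupancy
#' \eqn{1/(T_{free} (\mu - \gamma V))} on \code{(V_reset, V_theta)} is
#' returned.
#'
#' @param params a \code{\link{model_params}}.
#' @param rate_nu stationary rate (>= 0), typically from
#'   \code{\link{self_consistent_rate}}.
#' @param mod dendritic modulation (for the effective single-spike strength).
#' @param n_grid number of grid points (>= 2000).
#' @return a \code{"stationary_density"} with fields \code{grid},
#'   \code{density}, \code{rate_nu}, \code{source = "diffusion"}.
#' @export
stationary_density_diffusion <- function(params, rate_nu,
                                         mod = dendritic_modulation(linear = TRUE),
                                         n_grid = 2001) {
  stopifnot(inherits(params, "model_params"), rate_nu >= 0, n_grid >= 2000)
  g <- params$gamma; Vt <- params$V_theta; Vr <- params$V_reset
  m <- diffusion_moments(params, mod, rate_nu)
  mu <- m[["mu"]]; D <- m[["D"]]
  if (D <= 0) {
    # deterministic supra-threshold flow: occupancy ~ 1 / speed
    Tf <- free_period(params)
    grid <- seq(Vr, Vt, length.out = n_grid)
    dens <- 1 / (Tf * (mu - g * grid))
    return(new_stationary_density(grid, dens, rate_nu, "diffusion", params))
  }
  mu_V <- mu / g
  sig_V <- sqrt(D / (2 * g))
  V_low <- Vt - 10 * max(sig_V, Vt - Vr)
  # at least half the grid resolves (V_reset, V_theta), where the mass sits
  n_below <- min(n_grid %/% 2L,
                 max(3L, round(n_grid * (Vr - V_low) / (Vt - V_low))))
  grid <- c(seq(V_low, Vr, length.out = n_below),
            seq(Vr, Vt, length.out = n_grid - n_below + 1L)[-1])
  a <- g / D
  q <- a * (grid - mu_V)^2
  i_r <- n_below  # index of V_reset
  n <- length(grid)
  # S[j] = int_{V_j}^{V_t} exp(q(u) - q(V_j)) du by downward-stable
  # recursion; each cell integrates the locally linearized exponent exactly,
  # which stays accurate even when the boundary layer (width D/gamma) is far
  # narrower than the grid spacing
  S <- numeric(n)
  for (j in (n - 1):i_r) {
    dx <- grid[j + 1] - grid[j]
    r <- exp(q[j + 1] - q[j])   # <= 1 while moving away from mu_V
    qd_mid <- 2 * a * (grid[j] + dx / 2 - mu_V)  # dq/dV at the cell midpoint
    qd_l <- 2 * a * (grid[j] - mu_V)             # and at the left edge
    local <- if (abs(qd_mid * dx) < 1e-8) dx
    else if (qd_l * dx < -30) -1 / qd_l  # Laplace limit, boundary layer << dx
    else expm1(qd_mid * dx) / qd_mid
    S[j] <- local + r * S[j + 1]
  }
  dens <- numeric(n)
  dens[i_r:n] <- S[i_r:n]
  if (i_r > 1) {
    jlow <- 1:(i_r - 1)
    dens[jlow] <- exp(q[i_r] - q[jlow]) * S[i_r]
  }
  new_stationary_density(grid, dens, rate_nu, "diffusion", params)
}

#' Empirical membrane-potential density from simulation snapshots
#'
#' The semi-analytic pathway: a normalized histogram of directly measured
#' membrane potentials (see \code{\link{potential_snapshots}}), replacing the
#' diffusion approximation while keeping the rest of the theory unchanged.
#'
#' @param snapshots numeric vector of membrane potentials from equilibrated,
#'   unstimulated background activity.
#' @param params a \code{\link{model_params}}.
#' @param rate_nu stationary rate to record (optional; measured rates can be
#'   attached by the caller).
#' @param n_grid number of grid points.
#' @return a \code{"stationary_density"} with \code{source = "empirical"}.
#' @export
empirical_density <- function(snapshots, params, rate_nu = NA_real_,
                              n_grid = 2001) {
  stopifnot(inherits(params, "model_params"), n_grid >= 100)
  if (length(snapshots) < 1e4)
    warning("empirical_density: fewer than 1e4 samples; excitation probabilities will be noisy")
  Vt <- params$V_theta
  lo <- min(c(snapshots, params$V_reset)) - 1e-9
  breaks <- seq(lo, Vt, length.out = n_grid + 1)
  h <- graphics::hist(pmin(snapshots, Vt), breaks = breaks, plot = FALSE)
  grid <- h$mids
  new_stationary_density(grid, h$density, rate_nu, "empirical", params)
}

#' Excitation probability of a background neuron
#'
#' The probability that an equilibrated neuron is driven to or above
#' threshold by an instantaneous input of total strength \code{lam}: the
#' cumulative membrane-potential distribution from the right,
#' \eqn{F(\lambda) = \int_{V_\theta - \lambda}^{V_\theta} P(V)\,dV} for
#' \eqn{\lambda > 0} and 0 otherwise.
#'
#' @param lam total input strength(s), signed (potential units).
#' @param dens a \code{\link{stationary_density_diffusion}} /
#'   \code{\link{empirical_density}} object.
#' @return probability vector, non-decreasing in \code{lam}.
#' @export
excitation_probability <- function(lam, dens) {
  stopifnot(inherits(dens, "stationary_density"))
  out <- numeric(length(lam))
  pos <- lam > 0
  out[pos] <- pmin(1, dens$Fright(dens$V_theta - lam[pos]))
  out
}

#' Sample membrane potentials from a stationary density
#'
#' Inverse-CDF sampling on the density grid; used to prepare frozen network
#' states with independently drawn potentials for single-wave experiments.
#'
#' @param dens a \code{"stationary_density"}.
#' @param n number of samples.
#' @return numeric vector of potentials (strictly below threshold).
#' @export
sample_potentials <- function(dens, n) {
  stopifnot(inherits(dens, "stationary_density"))
  dx <- diff(dens$grid)
  cdf <- cumsum(c(0, dx * (dens$density[-1] +
                             dens$density[-length(dens$density)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  qf <- stats::approxfun(cdf[keep], dens$grid[keep], rule = 2)
  pmin(qf(stats::runif(n)), dens$V_theta - 1e-9)
}

#' Joint distribution of synchronous inputs from a group
#'
#' When a synchronized group of \code{g} neurons fires, a given neuron
#' receives \code{m} excitatory and \code{l} inhibitory spikes, where
#' \code{(m, l)} is trinomial with \code{g} trials and per-trial
#' probabilities \code{p_conn * p_exc}, \code{p_conn * p_inh},
#' \code{1 - p_conn}.  For large \code{g} the pmf is restricted to a central
#' window of \code{window_sd} standard deviations in each margin (the rest of
#' the mass is below double precision at the defaults).
#'
#' @param g group size (0 <= g <= N).
#' @param params a \code{\link{model_params}}.
#' @param window_sd half-width of the truncation window in marginal SDs
#'   (\code{Inf} for the full support).
#' @return list with integer vectors \code{m}, \code{l} and matrix \code{P}
#'   (rows \code{m}, columns \code{l}) summing to 1 (up to the truncated
#'   tail).
#' @export
group_input_distribution <- function(g, params, window_sd = Inf) {
  stopifnot(inherits(params, "model_params"), g >= 0, g <= params$N)
  qe <- params$p_conn * params$p_exc
  qi <- params$p_conn * params$p_inh
  if (g == 0 || is.infinite(window_sd)) {
    m <- 0:g
  } else {
    c0 <- g * qe; s0 <- sqrt(g * qe * (1 - qe))
    m <- max(0, floor(c0 - window_sd * s0)):min(g, ceiling(c0 + window_sd * s0))
  }
  if (g == 0 || is.infinite(window_sd)) {
    l <- 0:g
  } else {
    c0 <- g * qi; s0 <- sqrt(g * qi * (1 - qi))
    l <- max(0, floor(c0 - window_sd * s0)):min(g, ceiling(c0 + window_sd * s0))
  }
  Pm <- stats::dbinom(m, g, qe)
  # conditional on m, l ~ Binomial(g - m, qi / (1 - qe))
  qcond <- if (qe < 1) qi / (1 - qe) else 0
  P <- matrix(0, length(m), length(l), dimnames = list(m = m, l = l))
  for (k in seq_along(m)) {
    P[k, ] <- Pm[k] * stats::dbinom(l, g - m[k], qcond)
  }
  list(m = m, l = l, P = P)
}

#' Probability that a neuron spikes in response to a synchronous pulse
#'
#' Mean-field response probability
#' \deqn{p(g) = \sum_{m,l} P(m,l\,|\,g)\; F(\sigma(m \epsilon_e) + l
#' \epsilon_i),}
#' where the excitatory inputs are combined through the dendritic modulation
#' and the inhibitory ones add linearly.  Exact trinomial summation for
#' \code{g <= g_exact}; beyond that the trinomial is truncated to its central
#' 8-SD window (normal-concentration regime), which is accurate to double
#' precision.
#'
#' @param g group size(s).
#' @param params a \code{\link{model_params}}.
#' @param mod a \code{\link{dendritic_modulation}}.
#' @param dens a \code{"stationary_density"}.
#' @param g_exact switch point between exact and windowed summation.
#' @return numeric vector of response probabilities in [0, 1].
#' @export
spike_response_probability <- function(g, params, mod, dens, g_exact = 300) {
  vapply(g, function(gi) {
    if (gi == 0) return(0)
    win <- if (gi <= g_exact) Inf else 8
    gd <- group_input_distribution(gi, params, window_sd = win)
    lam <- outer(sigma_modulate(gd$m * params$eps_exc, mod),
                 gd$l * params$eps_inh, "+")
    Fv <- excitation_probability(as.vector(lam), dens)
    sum(gd$P * Fv)
  }, numeric(1))
}

#' Fit the binomial group-size transition model
#'
#' The Markov description of chain propagation: after a pulse of size
#' \code{g}, the \code{g} participating neurons are refractory (reset) and
#' each of the remaining \code{N - g} neurons fires independently with
#' probability \code{p(g)} (see \code{\link{spike_response_probability}}),
#' so the next group size follows \code{Binomial(N - g, p(g))} with
#' conditional expectation \eqn{\hat E(g) = (N - g)\,p(g)}.
#'
#' @param params a \code{\link{model_params}}.
#' @param mod a \code{\link{dendritic_modulation}}.
#' @param dens a \code{"stationary_density"} (diffusion or empirical); if
#'   NULL the diffusion pathway at the self-consistent rate is used.
#' @param g group sizes on which to evaluate \code{p(g)}; default all of
#'   \code{0:N}.
#' @param g_exact see \code{\link{spike_response_probability}}.
#' @return an object of class \code{"transition_model"} with fields
#'   \code{N}, \code{g}, \code{p_g}, \code{E_hat}, \code{dens_source}.
#' @examples
#' p <- model_params(N = 300, p_conn = 0.1, p_exc = 0.8, eps_exc = 0.01,
#'                   eps_inh = -0.04, I_ext = 1.3)
#' tm <- transition_model(p, dendritic_modulation(linear = TRUE))
#' tm
#' @export
transition_model <- function(params, mod, dens = NULL, g = 0:params$N,
                             g_exact = 300) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(dens)) {
    nu <- self_consistent_rate(params, mod)
    dens <- stationary_density_diffusion(params, nu, mod)
  }
  g <- sort(unique(as.integer(g)))
  stopifnot(all(g >= 0), all(g <= params$N))
  p_g <- spike_response_probability(g, params, mod, dens, g_exact = g_exact)
  structure(list(N = params$N, g = g, p_g = p_g,
                 E_hat = (params$N - g) * p_g,
                 params = params, mod = mod,
                 dens_source = dens$source, rate_nu = dens$rate_nu),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "Group-size transition model (N = %d, density: %s, nu = %.4g)\n",
    x$N, x$dens_source, x$rate_nu))
  cat(sprintf("  p(g) on %d group sizes; max E_hat = %.1f at g = %d\n",
              length(x$g), max(x$E_hat), x$g[which.max(x$E_hat)]))
  fp <- find_fixed_points(x)
  print(fp)
  invisible(x)
}

#' @export
summary.transition_model <- function(object, ...) {
  list(N = object$N, dens_source = object$dens_source,
       rate_nu = object$rate_nu,
       fixed_points = find_fixed_points(object),
       E_hat = stats::setNames(object$E_hat, object$g))
}

#' @export
plot.transition_model <- function(x, g_max = NULL, ...) {
  if (is.null(g_max)) {
    top <- max(c(x$g[x$E_hat > 0.5], 20))
    g_max <- min(x$N, 2 * top)
  }
  keep <- x$g <= g_max
  plot(x$g[keep], x$E_hat[keep], type = "l", col = "blue",
       xlab = "group size g", ylab = expression(hat(E)(g)), ...)
  graphics::abline(0, 1, lty = 2)
  fp <- find_fixed_points(x)
  if (nrow(fp$points))
    graphics::points(fp$points$g, fp$points$g,
                     pch = ifelse(fp$points$stability == "stable", 19, 1))
  invisible(x)
}

#' Interpolated expectation curve of a transition model
#'
#' Piecewise-linear interpolation of \eqn{\hat E(g)} between the evaluated
#' group sizes (no smoothing).
#'
#' @param model a \code{\link{transition_model}}.
#' @return a function \code{Ehat(g)} valid on \code{[0, N]}; the evaluated
#'   values are available as \code{data.frame(g, p_g, E_hat)} via
#'   \code{\link{expectation_curve}}.
#' @export
expectation_interp <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  stats::approxfun(model$g, model$E_hat, rule = 2)
}

#' Expectation curve table
#'
#' @param model a \code{\link{transition_model}}.
#' @return data.frame with columns \code{g}, \code{p_g}, \code{E_hat}.
#' @export
expectation_curve <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  data.frame(g = model$g, p_g = model$p_g, E_hat = model$E_hat)
}

#' Transition probability mass function
#'
#' \eqn{P(g' | g) = \mathrm{Binomial}(g'; N - g, p(g))}: the distribution of
#' the next group size given the current one.
#'
#' @param model a \code{\link{transition_model}}.
#' @param g current group size (must be one of \code{model$g}).
#' @return numeric vector of probabilities over \code{g' = 0 .. N - g}.
#' @export
transition_pmf <- function(model, g) {
  stopifnot(inherits(model, "transition_model"))
  i <- match(g, model$g)
  if (is.na(i)) stop("transition_pmf: g was not evaluated in this model")
  stats::dbinom(0:(model$N - g), model$N - g, model$p_g[i])
}

#' Sample next group sizes from the transition model
#'
#' @param model a \code{\link{transition_model}}.
#' @param g current group size.
#' @param n number of samples.
#' @param seed optional seed.
#' @return integer vector of sampled next group sizes.
#' @export
sample_transition <- function(model, g, n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  i <- match(g, model$g)
  if (is.na(i)) stop("sample_transition: g was not evaluated in this model")
  stats::rbinom(n, model$N - g, model$p_g[i])
}

#' Export a transition model to CSV
#'
#' Writes columns \code{g}, \code{p_g}, \code{E_hat}; optionally the full
#' transition pmfs in sparse long format (\code{g}, \code{g_prime},
#' \code{prob}) keeping entries >= \code{prob_min}.
#'
#' @param model a \code{\link{transition_model}}.
#' @param file output CSV path.
#' @param pmf_file optional path for the sparse pmf table.
#' @param prob_min sparsity threshold for the pmf export.
#' @export
write_transition_csv <- function(model, file, pmf_file = NULL,
                                 prob_min = 1e-12) {
  utils::write.csv(expectation_curve(model), file, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(pmf_file)) {
    rows <- lapply(model$g, function(g) {
      p <- transition_pmf(model, g)
      keep <- p >= prob_min
      data.frame(g = g, g_prime = which(keep) - 1L, prob = p[keep])
    })
    utils::write.csv(do.call(rbind, rows), pmf_file, row.names = FALSE,
                     quote = FALSE)
  }
}

#' Per-network exact response probability
#'
#' For one frozen coupling matrix, the probability that a random non-sender
#' neuron fires in response to a pulse sent by a uniformly random
#' \code{g}-subset of neurons: for each neuron the distribution of received
#' (excitatory, inhibitory) input counts is multivariate hypergeometric over
#' its actual in-neighborhood, combined with \code{F} exactly.  This is the
#' quenched-topology counterpart of
#' \code{\link{spike_response_probability}}, used as an oracle against
#' single-wave dynamics.
#'
#' @param matrix a \code{\link{build_network}} coupling matrix.
#' @param g group size.
#' @param params a \code{\link{model_params}}.
#' @param mod a \code{\link{dendritic_modulation}}.
#' @param dens a \code{"stationary_density"}.
#' @return mean per-neuron response probability.
#' @export
network_response_probability <- function(matrix, g, params, mod, dens) {
  stopifnot(inherits(matrix, "coupling_matrix"), g >= 1, g <= matrix$N)
  N <- matrix$N
  exc_in <- tabulate(matrix$post[matrix$w > 0], nbins = N)
  inh_in <- tabulate(matrix$post[matrix$w < 0], nbins = N)
  Fcache <- new.env()
  p_i <- vapply(seq_len(N), function(i) {
    ke <- exc_in[i]; ki <- inh_in[i]; k0 <- N - 1 - ke - ki
    ms <- 0:min(ke, g)
    tot <- 0
    logden <- lchoose(N - 1, g)
    for (m in ms) {
      ls <- 0:min(ki, g - m)
      lp <- lchoose(ke, m) + lchoose(ki, ls) + lchoose(k0, g - m - ls) -
        logden
      w <- exp(lp)
      lam <- sigma_modulate(m * params$eps_exc, mod) + ls * params$eps_inh
      tot <- tot + sum(w * excitation_probability(lam, dens))
    }
    tot
  }, numeric(1))
  mean(p_i)
}
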