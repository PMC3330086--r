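# Fixed points and iteration of the group-size map.

#' Fixed points of the expectation curve
#'
#' Locates all intersections of the piecewise-linearly interpolated
#' expectation curve \eqn{\hat E(g)} with the diagonal and classifies their
#' stability by the interpolated slope (\code{|slope| < 1} stable,
#' \code{> 1} unstable, \code{== 1} marginal).  The absorbing point
#' \code{g = 0} is always reported.  When the pattern
#' stable < unstable < stable is present the named points
#' \eqn{\psi_-} (lower stable level, spontaneous synchronization),
#' \eqn{\psi_0} (unstable initiation threshold) and \eqn{\psi_+} (stable
#' propagation size) are identified.
#'
#' @param x a \code{\link{transition_model}}, or a numeric vector of
#'   \eqn{\hat E} values (then supply \code{g}).
#' @param g group sizes matching \code{x} when \code{x} is numeric.
#' @return an object of class \code{"fixed_point_set"}: data.frame
#'   \code{points} (columns \code{g}, \code{stability}, \code{slope}) plus
#'   \code{psi_minus}, \code{psi_zero}, \code{psi_plus} (NA when absent).
#' @export
find_fixed_points <- function(x, g = NULL) {
  if (inherits(x, "transition_model")) {
    g <- x$g; E <- x$E_hat
  } else {
    E <- as.numeric(x)
    if (is.null(g)) g <- seq_along(E) - 1
  }
  stopifnot(length(g) == length(E), !is.unsorted(g))
  h <- E - g
  n <- length(g)
  slopes <- diff(E) / diff(g)
  roots <- numeric(0); rslope <- numeric(0)
  eps <- 1e-12 * max(1, max(abs(E)))
  for (k in seq_len(n - 1)) {
    h0 <- h[k]; h1 <- h[k + 1]
    if (abs(h0) <= eps) {
      sl <- if (k == 1) slopes[1] else mean(slopes[c(k - 1, k)])
      roots <- c(roots, g[k]); rslope <- c(rslope, sl)
    } else if (h0 * h1 < 0) {
      r <- g[k] + h0 * (g[k + 1] - g[k]) / (h0 - h1)
      roots <- c(roots, r); rslope <- c(rslope, slopes[k])
    }
  }
  if (abs(h[n]) <= eps) {
    roots <- c(roots, g[n]); rslope <- c(rslope, slopes[n - 1])
  }
  if (!any(roots == g[1] & g[1] == 0) && g[1] == 0) {
    # absorbing origin always reported even if E(0) > 0 numerically
    roots <- c(0, roots); rslope <- c(slopes[1], rslope)
  }
  keep <- !duplicated(round(roots, 9))
  roots <- roots[keep]; rslope <- rslope[keep]
  ord <- order(roots)
  roots <- roots[ord]; rslope <- rslope[ord]
  stab <- ifelse(abs(abs(rslope) - 1) < 1e-9, "marginal",
                 ifelse(abs(rslope) < 1, "stable", "unstable"))
  pts <- data.frame(g = roots, stability = stab, slope = rslope)
  psi_minus <- psi_zero <- psi_plus <- NA_real_
  st <- pts$g[pts$stability == "stable"]
  un <- pts$g[pts$stability == "unstable"]
  if (length(st) >= 2 && length(un) >= 1) {
    cand <- un[un < max(st) & vapply(un, function(u) any(st < u), logical(1))]
    if (length(cand)) {
      psi_zero <- max(cand)
      psi_plus <- min(st[st > psi_zero])
      psi_minus <- max(st[st < psi_zero])
    }
  }
  if (is.na(psi_plus) && length(st)) psi_minus <- min(st)
  structure(list(points = pts, psi_minus = psi_minus, psi_zero = psi_zero,
                 psi_plus = psi_plus),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat("Fixed points of the group-size map:\n")
  if (nrow(x$points) == 0) {
    cat("  (none)\n")
  } else {
    for (i in seq_len(nrow(x$points)))
      cat(sprintf("  g* = %8.2f  %s (slope %.3f)\n", x$points$g[i],
                  x$points$stability[i], x$points$slope[i]))
  }
  if (!is.na(x$psi_plus))
    cat(sprintf("  psi- = %.2f < psi0 = %.2f < psi+ = %.2f (bistable)\n",
                x$psi_minus, x$psi_zero, x$psi_plus))
  else if (!is.na(x$psi_minus))
    cat(sprintf("  single stable level psi- = %.2f (no persistent propagation)\n",
                x$psi_minus))
  invisible(x)
}

#' Export a fixed-point set as JSON
#'
#' @param fp a \code{\link{find_fixed_points}} result.
#' @param file output path.
#' @export
write_fixed_points_json <- function(fp, file) {
  jsonlite::write_json(
    list(points = fp$points, psi_minus = fp$psi_minus,
         psi_zero = fp$psi_zero, psi_plus = fp$psi_plus),
    file, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Deterministic iteration of the group-size map
#'
#' Iterates \eqn{g_{k+1} = \mathrm{round}(\hat E(g_k))} (round half up;
#' fixed-point locations are real-valued) using the piecewise-linear
#' interpolation of the expectation curve, and detects convergence to a
#' fixed point or to a periodic orbit of period up to 8.
#'
#' @param model a \code{\link{transition_model}} (or anything accepted by
#'   \code{\link{find_fixed_points}} is not required here - a numeric
#'   expectation curve plus \code{g} also works).
#' @param g0 initial group size in \code{[0, N]}.
#' @param K number of iterations.
#' @param g optional group sizes when \code{model} is a numeric curve.
#' @return integer vector \code{g_0 .. g_K}; attributes \code{period} (NA if
#'   no cycle detected) and \code{cycle} (the repeating values).
#' @export
iterate_deterministic <- function(model, g0, K, g = NULL) {
  if (inherits(model, "transition_model")) {
    Ef <- expectation_interp(model); N <- model$N
  } else {
    E <- as.numeric(model)
    if (is.null(g)) g <- seq_along(E) - 1
    Ef <- stats::approxfun(g, E, rule = 2); N <- max(g)
  }
  stopifnot(g0 >= 0, g0 <= N, K >= 1)
  out <- integer(K + 1)
  out[1] <- as.integer(g0)
  for (k in seq_len(K)) {
    nxt <- floor(Ef(out[k]) + 0.5)  # round half up
    out[k + 1] <- as.integer(min(max(nxt, 0), N))
  }
  period <- NA_integer_; cycle <- NULL
  for (p in 1:8) {
    if (K + 1 >= 3 * p) {
      tail_v <- out[(K + 1 - 2 * p + 1):(K + 1)]
      if (all(tail_v[1:p] == tail_v[(p + 1):(2 * p)])) {
        period <- p; cycle <- tail_v[1:p]
        break
      }
    }
  }
  structure(out, period = period, cycle = cycle)
}

#' Stochastic iteration of the group-size map
#'
#' Samples a chain \eqn{g_{k+1} \sim \mathrm{Binomial}(N - g_k, p(g_k))}
#' from the transition model; the origin is absorbing.
#'
#' @param model a \code{\link{transition_model}}.
#' @param g0 initial group size.
#' @param K number of steps.
#' @param seed optional seed.
#' @return integer vector \code{g_0 .. g_K}.
#' @export
iterate_stochastic <- function(model, g0, K, seed = NULL) {
  stopifnot(inherits(model, "transition_model"), g0 >= 0, g0 <= model$N)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pf <- stats::approxfun(model$g, model$p_g, rule = 2)
  out <- integer(K + 1)
  out[1] <- as.integer(g0)
  for (k in seq_len(K)) {
    gk <- out[k]
    if (gk == 0) break  # absorbing: remaining entries stay 0
    out[k + 1] <- stats::rbinom(1, model$N - gk, pf(gk))
  }
  out
}

#' Simulate group-size chains from a transition model
#'
#' \code{stats::simulate} method: draws \code{nsim} independent stochastic
#' chains (see \code{\link{iterate_stochastic}}).
#'
#' @param object a \code{\link{transition_model}}.
#' @param nsim number of chains.
#' @param seed optional seed.
#' @param g0 initial group size.
#' @param K steps per chain.
#' @param ... unused.
#' @return integer matrix with \code{nsim} rows and \code{K + 1} columns.
#' @export
simulate.transition_model <- function(object, nsim = 1, seed = NULL,
                                      g0, K = 50, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  t(vapply(seq_len(nsim), function(i) iterate_stochastic(object, g0, K),
           integer(K + 1)))
}

#' Exact mean absorption time of the group-size chain
#'
#' Builds the explicit \code{(N+1)}-state transition matrix of the model
#' (absorbing at 0 since \code{p(0) = 0}) and returns the expected number of
#' steps to absorption from each transient state via the fundamental matrix,
#' \eqn{t = (I - Q)^{-1} 1}.  Intended for small N.
#'
#' @param model a \code{\link{transition_model}} evaluated on all of
#'   \code{0:N}.
#' @return numeric vector \code{t[g]} for \code{g = 1 .. N}.
#' @export
absorption_time_exact <- function(model) {
  stopifnot(inherits(model, "transition_model"),
            identical(model$g, 0:model$N))
  N <- model$N
  if (model$p_g[1] != 0)
    stop("absorption_time_exact: state 0 is not absorbing (p(0) > 0)")
  Q <- matrix(0, N, N)
  for (gi in 1:N) {
    p <- stats::dbinom(0:(N - gi), N - gi, model$p_g[gi + 1])
    Q[gi, seq_len(N - gi)] <- p[-1]  # transitions to 1 .. N - gi
  }
  drop(solve(diag(N) - Q, rep(1, N)))
}

#' Monte-Carlo measurement of the group-size transition
#'
#' The dynamical validation oracle of the binomial transition model: for
#' each trial the network is equilibrated from a fresh random initial
#' condition, a synchronous pulse of \code{g} neurons is initiated by
#' external stimulation, and the size of the subsequent pulse (spikes
#' exactly one delay later) is measured.
#'
#' @param params a \code{\link{model_params}}.
#' @param matrix a \code{\link{build_network}} coupling matrix.
#' @param mod a \code{\link{dendritic_modulation}}.
#' @param g initial pulse size.
#' @param n_trials number of independent trials.
#' @param seed integer seed.
#' @param t_eq equilibration time per trial.
#' @param stim_mode \code{"random"} (uniform random g-subset) or
#'   \code{"prefix"}.
#' @param guard_rate simulation abort guard (spikes per unit time, 0 = off).
#' @return list with \code{g}, \code{g1} (per-trial next sizes),
#'   \code{mean}, \code{freq} (frequency table) and \code{n_aborted}.
#' @export
monte_carlo_transition <- function(params, matrix, mod, g, n_trials,
                                   seed = NULL, t_eq = 20,
                                   stim_mode = "random", guard_rate = 0) {
  stopifnot(n_trials >= 1, g >= 0, g <= params$N)
  if (!is.null(seed)) set.seed(as.integer(seed))
  g1 <- integer(n_trials)
  n_ab <- 0L
  for (tr in seq_len(n_trials)) {
    st <- equilibrate(params, matrix, mod, t_eq = t_eq,
                      guard_rate = guard_rate)
    if (isTRUE(attr(attr(st, "raster"), "aborted"))) {
      n_ab <- n_ab + 1L; g1[tr] <- NA_integer_; next
    }
    if (g == 0) { g1[tr] <- 0L; next }
    t0 <- st$t_now + 0.5 * params$tau
    stim <- stimulus_protocol(t0, list(stim_target_set(params$N, g,
                                                       stim_mode)))
    ras <- simulate_network(params, matrix, mod, duration = 2 * params$tau,
                            stim = stim, state = st,
                            guard_rate = guard_rate)
    if (isTRUE(attr(ras, "aborted"))) {
      n_ab <- n_ab + 1L; g1[tr] <- NA_integer_; next
    }
    ch <- extract_chain(ras, t0 = t0, tau = params$tau, horizon = 1)
    g1[tr] <- if (length(ch$sizes) >= 2) ch$sizes[2] else 0L
  }
  ok <- !is.na(g1)
  list(g = g, g1 = g1[ok], mean = mean(g1[ok]),
       freq = table(g1[ok]), n_aborted = n_ab)
}
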