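#' Stimulation protocol
#'
#' A list of external supra-threshold pulses: at each \code{time}, every
#' neuron in the corresponding target set is forced to spike immediately
#' (tagged \code{"stimulus"} in the raster).  This is how chains of
#' synchronous activity are initiated.
#'
#' @param times numeric vector of pulse times (>= 0).
#' @param sets list of integer vectors of 1-based neuron ids (or a single
#'   vector, recycled for one pulse).
#' @return an object of class \code{"stimulus_protocol"}.
#' @export
stimulus_protocol <- function(times, sets) {
  if (!is.list(sets)) sets <- list(sets)
  stopifnot(length(times) == length(sets), all(times >= 0),
            all(lengths(sets) > 0))
  ord <- order(times)
  structure(list(times = times[ord], sets = lapply(sets[ord], as.integer)),
            class = "stimulus_protocol")
}

#' Pick a stimulus target set
#'
#' Default is a uniformly random subset of size \code{g0}; with
#' \code{mode = "prefix"} the first \code{g0} neurons are used instead
#' (reproduction-friendly deterministic choice).
#'
#' @param N network size.
#' @param g0 group size.
#' @param mode \code{"random"} or \code{"prefix"}.
#' @return integer vector of neuron ids.
#' @export
stim_target_set <- function(N, g0, mode = c("random", "prefix")) {
  mode <- match.arg(mode)
  stopifnot(g0 >= 1, g0 <= N)
  if (mode == "prefix") seq_len(g0) else sample.int(N, g0)
}

new_sim_state <- function(phases, transit_dt, transit_sender, t_now = 0) {
  structure(list(phases = phases,
                 transit = data.frame(dt = transit_dt,
                                      sender = as.integer(transit_sender)),
                 t_now = t_now),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("Simulation state: %d neurons at t = %g, %d spikes in transit\n",
              length(x$phases), x$t_now, nrow(x$transit)))
  invisible(x)
}

new_spike_raster <- function(time, neuron, tag_int, N, aborted = FALSE,
                             abort_reason = "") {
  tag <- factor(c("background", "chain", "stimulus")[tag_int + 1L],
                levels = c("background", "chain", "stimulus"))
  ord <- order(time, neuron)
  structure(data.frame(time = time[ord], neuron = as.integer(neuron[ord]),
                       tag = tag[ord]),
            N = N, aborted = aborted, abort_reason = abort_reason,
            class = c("spike_raster", "data.frame"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("Spike raster: %d spikes, %d neurons, t in [%g, %g]%s\n",
              nrow(x), attr(x, "N"),
              if (nrow(x)) min(x$time) else NA, if (nrow(x)) max(x$time) else NA,
              if (isTRUE(attr(x, "aborted")))
                paste0("  [ABORTED: ", attr(x, "abort_reason"), "]") else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' @export
plot.spike_raster <- function(x, max_neurons = 200, ...) {
  keep <- x$neuron <= max_neurons
  cols <- c(background = "grey30", chain = "grey60", stimulus = "red")
  plot(x$time[keep], x$neuron[keep], pch = ".", cex = 2,
       col = cols[as.character(x$tag[keep])],
       xlab = "time (membrane time constants)", ylab = "neuron", ...)
  invisible(x)
}

run_segment <- function(state, params, matrix, mod, duration,
                        stim = NULL, guard_rate = 0, max_spikes = 2e7) {
  stopifnot(inherits(params, "model_params"),
            inherits(matrix, "coupling_matrix"),
            inherits(mod, "dendritic_modulation"),
            params$N == matrix$N, duration >= 0)
  if (is.null(stim)) {
    stim_times <- numeric(0); stim_sets <- list()
  } else {
    stopifnot(inherits(stim, "stimulus_protocol"))
    rel <- stim$times - state$t_now
    keep <- rel >= 0 & rel <= duration
    stim_times <- rel[keep]
    stim_sets <- lapply(stim$sets[keep], function(s) s - 1L)
  }
  res <- .sim_core(params$N,
                   matrix$out_ptr, matrix$post - 1L, matrix$w,
                   state$phases, state$transit$dt, state$transit$sender - 1L,
                   stim_times, stim_sets, duration,
                   params$gamma, params$I_ext, params$V_theta, params$V_reset,
                   params$tau,
                   mod$theta_b, mod$theta_s, mod$s_sat, mod$linear,
                   guard_rate, max_spikes)
  raster <- new_spike_raster(res$times + state$t_now, res$ids + 1L, res$tags,
                             params$N, res$aborted, res$abort_reason)
  state_out <- new_sim_state(res$phases_end, res$transit_dt,
                             res$transit_sender + 1L,
                             t_now = state$t_now + res$t_end)
  list(raster = raster, state = state_out)
}

#' Draw a random initial condition and equilibrate the network
#'
#' Initial phases are drawn uniformly on \code{[0, phi_theta)} and
#' \code{n_transit_init} random spikes are placed in transit (random senders,
#' arrival times uniform on \code{[0, tau)}); the network is then evolved for
#' \code{t_eq} so the membrane-potential distribution relaxes to its
#' stationary background shape.  With \code{t_eq = 0} the sampled initial
#' condition is returned unchanged.
#'
#' @param params a \code{\link{model_params}}.
#' @param matrix a \code{\link{build_network}} coupling matrix.
#' @param mod a \code{\link{dendritic_modulation}}.
#' @param t_eq equilibration time (membrane time constants, >= 0); default 50.
#' @param seed integer seed (optional; uses the current RNG state if NULL).
#' @param n_transit_init number of random spikes initially in transit;
#'   defaults to the mean in-degree \code{round(N * p_conn)}.
#' @param guard_rate abort threshold, network spikes per unit time (0 = off).
#' @return a \code{"sim_state"}; the equilibration \code{spike_raster} is
#'   attached as attribute \code{"raster"}.
#' @export
equilibrate <- function(params, matrix, mod, t_eq = 50, seed = NULL,
                        n_transit_init = NULL, guard_rate = 0) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  N <- params$N
  if (is.null(n_transit_init)) n_transit_init <- round(N * params$p_conn)
  phi_theta <- free_period(params)
  phases <- stats::runif(N, 0, phi_theta)
  state <- new_sim_state(phases,
                         stats::runif(n_transit_init, 0, params$tau),
                         sample.int(N, n_transit_init, replace = TRUE))
  if (t_eq > 0) {
    seg <- run_segment(state, params, matrix, mod, t_eq,
                       guard_rate = guard_rate)
    state <- seg$state
    attr(state, "raster") <- seg$raster
  } else {
    attr(state, "raster") <- new_spike_raster(numeric(0), integer(0),
                                              integer(0), N)
  }
  state
}

#' Run the event-driven network simulation
#'
#' Exact event-driven integration of the delayed pulse-coupled LIF network:
#' the smallest pseudo-spike time (time to the next free threshold crossing)
#' is compared with the next spike-arrival time; free evolution between
#' events is exact in phase representation.  All spikes arriving at one
#' instant form a wave whose summed excitatory strength passes through the
#' dendritic modulation before the linearly summed inhibition is added;
#' neurons driven to or above threshold fire at that same instant and their
#' spikes arrive \code{tau} later.  Stimulus pulses force immediate spiking
#' of their target sets.
#'
#' @inheritParams equilibrate
#' @param duration simulated time (> 0).
#' @param stim a \code{\link{stimulus_protocol}} or NULL; times are absolute
#'   (i.e. relative to the start of \code{state}, time 0 for a fresh run).
#' @param state an existing \code{"sim_state"} to continue from; if NULL a
#'   fresh random initial condition is drawn (no equilibration).
#' @param max_spikes hard cap on recorded spikes (memory guard).
#' @return a \code{spike_raster}; the final \code{"sim_state"} is attached as
#'   attribute \code{"state"}.
#' @examples
#' p <- model_params(N = 20, p_conn = 0.2, p_exc = 0.8, eps_exc = 0.01,
#'                   eps_inh = -0.04, I_ext = 1.3)
#' cm <- build_network(p, seed = 1)
#' r <- simulate_network(p, cm, dendritic_modulation(linear = TRUE),
#'                       duration = 10, seed = 2)
#' r
#' @export
simulate_network <- function(params, matrix, mod, duration, stim = NULL,
                             seed = NULL, state = NULL, guard_rate = 0,
                             max_spikes = 2e7) {
  stopifnot(duration > 0)
  if (is.null(state)) {
    state <- equilibrate(params, matrix, mod, t_eq = 0, seed = seed,
                         guard_rate = guard_rate)
  } else if (!is.null(seed)) set.seed(as.integer(seed))
  seg <- run_segment(state, params, matrix, mod, duration, stim = stim,
                     guard_rate = guard_rate, max_spikes = max_spikes)
  out <- seg$raster
  attr(out, "state") <- seg$state
  out
}

#' Deliver one synchronous wave to a frozen network state
#'
#' Applies a single synchronous pulse sent by \code{senders} to the network:
#' for each postsynaptic neuron the excitatory strengths from the senders are
#' summed and passed through the dendritic modulation, the inhibitory
#' strengths are added linearly, and the phase is updated synchronously from
#' the pre-delivery phases.  Used for single-step response measurements and
#' as the dynamical side of the binomial transition-model oracle.
#'
#' @param state a \code{"sim_state"} (only \code{phases} is used/updated).
#' @param senders integer vector of 1-based sender ids (all sharing one
#'   arrival time).
#' @param matrix a \code{coupling_matrix}.
#' @param mod a \code{dendritic_modulation}.
#' @param pf a \code{\link{phase_functions}}.
#' @return list with \code{fired} (ids that spike now) and the updated
#'   \code{state} (fired neurons reset to phase 0).
#' @export
deliver_wave <- function(state, senders, matrix, mod, pf) {
  stopifnot(inherits(state, "sim_state"), inherits(matrix, "coupling_matrix"),
            inherits(pf, "phase_functions"))
  senders <- as.integer(senders)
  idx <- unlist(lapply(senders, function(s)
    seq.int(matrix$out_ptr[s] + 1L, length.out = matrix$out_ptr[s + 1L] -
              matrix$out_ptr[s])), use.names = FALSE)
  if (length(idx) == 0)
    return(list(fired = integer(0), state = state))
  tgt <- matrix$post[idx]; w <- matrix$w[idx]
  exc <- rowsum(pmax(w, 0), tgt)
  inh <- rowsum(pmin(w, 0), tgt)
  touched <- as.integer(rownames(exc))
  lam <- sigma_modulate(exc[, 1], mod) + inh[, 1]
  upd <- apply_input(state$phases[touched], lam, pf)
  state$phases[touched] <- upd$phi_new
  list(fired = touched[upd$fired], state = state)
}

#' Membrane potentials of a simulation state
#'
#' Maps the per-neuron phases back to potentials through the LIF transfer
#' function.
#'
#' @param state a \code{"sim_state"}.
#' @param params the matching \code{\link{model_params}}.
#' @return numeric vector of potentials.
#' @export
membrane_potentials <- function(state, params) {
  phase_functions(params)$U(state$phases)
}

#' Collect membrane-potential snapshots from background activity
#'
#' Runs \code{n_runs} independent equilibrations and then records all N
#' potentials every \code{dt_snap} time units, \code{n_snaps} times per run.
#' The pooled samples feed \code{\link{empirical_density}} (the semi-analytic
#' pathway of the theory).
#'
#' @inheritParams equilibrate
#' @param n_runs independent runs (fresh initial conditions).
#' @param n_snaps snapshots per run.
#' @param dt_snap time between snapshots (decorrelation interval).
#' @return numeric vector of pooled membrane potentials.
#' @export
potential_snapshots <- function(params, matrix, mod, n_runs = 2, t_eq = 30,
                                n_snaps = 20, dt_snap = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- vector("list", n_runs * n_snaps)
  k <- 0
  for (r in seq_len(n_runs)) {
    st <- equilibrate(params, matrix, mod, t_eq = t_eq)
    for (s in seq_len(n_snaps)) {
      st0 <- run_segment(st, params, matrix, mod, dt_snap)
      st <- st0$state
      k <- k + 1
      out[[k]] <- membrane_potentials(st, params)
    }
  }
  unlist(out, use.names = FALSE)
}

#' Write / read a spike raster as CSV
#'
#' Columns \code{time}, \code{neuron} (1-based), \code{tag}; a comment
#' header line records the network size.
#'
#' @param x a \code{spike_raster}.
#' @param file path.
#' @export
write_raster_csv <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# dendsyn spike raster N=%d", attr(x, "N")), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(file) {
  hdr <- readLines(file, n = 1)
  N <- as.integer(sub(".*N=", "", hdr))
  d <- utils::read.csv(file, comment.char = "#")
  new_spike_raster(d$time, d$neuron,
                   match(d$tag, c("background", "chain", "stimulus")) - 1L, N)
}
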