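# Chain extraction, background pulse statistics, stability classification
# and the coupling-strength parameter scan.

#' Extract the synchrony chain from a spike raster
#'
#' Synchronized groups that are part of an externally initiated chain send
#' their spikes precisely at \code{t0 + k * tau} (the simulator makes this
#' exact up to the simultaneity tolerance), while background spikes occur at
#' at least slightly different times.  \code{g_k} is the number of spikes at
#' grid time \code{k}; the extracted sizes stop at the first \code{k >= 1}
#' with \code{g_k = 0} or at the horizon.
#'
#' @param raster a \code{spike_raster}.
#' @param t0 chain initiation time (the stimulus time).
#' @param tau transmission delay (grid spacing).
#' @param horizon maximum number of steps to extract.
#' @param tol simultaneity tolerance (defaults to \code{1e-9 * tau}).
#' @return an object of class \code{"chain"}: \code{t0}, \code{tau},
#'   \code{sizes} (\code{g_0 .. g_K}), \code{horizon}, and the retagged
#'   raster (chain spikes tagged \code{"chain"}) as attribute
#'   \code{"raster"}.
#' @export
extract_chain <- function(raster, t0, tau, horizon, tol = 1e-9 * tau) {
  stopifnot(inherits(raster, "spike_raster"), horizon >= 1)
  if (nrow(raster) && t0 < min(raster$time) - tol)
    stop("extract_chain: t0 precedes the raster start")
  sizes <- integer(horizon + 1)
  is_chain <- logical(nrow(raster))
  tk <- t0
  for (k in 0:horizon) {
    hit <- abs(raster$time - tk) <= tol
    sizes[k + 1] <- sum(hit)
    is_chain <- is_chain | hit
    if (k >= 1 && sizes[k + 1] == 0) {
      sizes <- sizes[seq_len(k + 1)]
      break
    }
    tk <- tk + tau  # repeated addition matches the simulator's arithmetic
  }
  out <- raster
  out$tag[is_chain & out$tag != "stimulus"] <- "chain"
  ch <- structure(list(t0 = t0, tau = tau, sizes = sizes,
                       horizon = horizon, N = attr(raster, "N")),
                  class = "chain")
  attr(ch, "raster") <- out
  ch
}

#' @export
print.chain <- function(x, ...) {
  K <- length(x$sizes) - 1
  cat(sprintf("Synchrony chain: g0 = %d, %d steps observed (horizon %d)\n",
              x$sizes[1], K, x$horizon))
  cat("  sizes:", paste(utils::head(x$sizes, 25), collapse = " "),
      if (length(x$sizes) > 25) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.chain <- function(x, ...) {
  plot(seq_along(x$sizes) - 1, x$sizes, type = "b", pch = 19,
       xlab = "chain step k", ylab = expression(g[k]), ...)
  invisible(x)
}

#' Write chain sizes as CSV (columns step, time, size)
#'
#' @param x a \code{"chain"}.
#' @param file output path.
#' @export
write_chain_csv <- function(x, file) {
  k <- seq_along(x$sizes) - 1
  utils::write.csv(data.frame(step = k, time = x$t0 + k * x$tau,
                              size = x$sizes),
                   file, row.names = FALSE, quote = FALSE)
}

#' Background pulse-size distribution
#'
#' Groups all non-chain spikes that share one spike time (within the
#' simulator's simultaneity tolerance) into spontaneous pulses and returns
#' the histogram of pulse sizes inside a time window.  Together with
#' \code{\link{extract_chain}} this partitions the raster into chain and
#' background spikes.
#'
#' @param raster a \code{spike_raster}.
#' @param chain the \code{"chain"} extracted from the same raster (NULL if
#'   no chain was initiated).
#' @param window numeric \code{c(t_start, t_end)}; spikes outside are
#'   ignored.
#' @param tol simultaneity tolerance.
#' @return an object of class \code{"pulse_size_distribution"}: a frequency
#'   table over pulse sizes plus \code{window} and \code{max_size}.
#' @export
background_pulses <- function(raster, chain = NULL, window = NULL,
                              tol = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (!is.null(chain)) {
    stopifnot(inherits(chain, "chain"))
    raster <- attr(chain, "raster")
    if (is.null(tol)) tol <- 1e-9 * chain$tau
  }
  if (is.null(tol)) tol <- 1e-12
  bg <- raster[raster$tag == "background", , drop = FALSE]
  if (!is.null(window))
    bg <- bg[bg$time >= window[1] & bg$time <= window[2], , drop = FALSE]
  if (nrow(bg) == 0) {
    return(structure(list(sizes = integer(0), freq = table(integer(0)),
                          window = window, max_size = 0L),
                     class = "pulse_size_distribution"))
  }
  ts <- sort(bg$time)
  grp <- cumsum(c(1, diff(ts) > tol))
  sizes <- as.integer(tabulate(grp))
  structure(list(sizes = sizes, freq = table(sizes), window = window,
                 max_size = max(sizes)),
            class = "pulse_size_distribution")
}

#' @export
print.pulse_size_distribution <- function(x, ...) {
  cat(sprintf("Background pulses: %d pulses, max size %d\n",
              length(x$sizes), x$max_size))
  if (length(x$sizes)) print(x$freq)
  invisible(x)
}

#' Classify one stimulation run
#'
#' Four-way stability classification: background activity is unstable if it
#' contains a synchronous pulse larger than \code{f_max * N} (before or
#' after chain initiation); propagation is stable if, with stable
#' background, the first \code{K_min} chain group sizes all exceed the
#' largest pulse observed in the background; otherwise propagation is
#' unstable (the chain decayed to the spontaneous level).
#'
#' @param chain a \code{"chain"}.
#' @param bg_pre,bg_post \code{"pulse_size_distribution"} objects for the
#'   pre-stimulus and post-stimulus background.
#' @param f_max background-instability threshold as a fraction of N.
#' @param K_min number of chain steps that must stay above background.
#' @return a character scalar of class \code{"stability_label"}: one of
#'   \code{"unstable_bg_pre"}, \code{"unstable_bg_post"},
#'   \code{"unstable_propagation"}, \code{"stable_propagation"}.
#' @export
classify_run <- function(chain, bg_pre, bg_post, f_max = 0.1, K_min = 20) {
  stopifnot(inherits(chain, "chain"),
            inherits(bg_pre, "pulse_size_distribution"),
            inherits(bg_post, "pulse_size_distribution"))
  if (K_min > chain$horizon)
    stop("classify_run: K_min exceeds the observed chain horizon")
  N <- chain$N
  lab <- if (bg_pre$max_size > f_max * N) {
    "unstable_bg_pre"
  } else if (bg_post$max_size > f_max * N) {
    "unstable_bg_post"
  } else {
    bg_max <- max(bg_pre$max_size, bg_post$max_size)
    gk <- chain$sizes[-1]  # g_1 .. g_K
    if (length(gk) < K_min) gk <- c(gk, integer(K_min - length(gk)))
    if (all(gk[seq_len(K_min)] > bg_max)) "stable_propagation"
    else "unstable_propagation"
  }
  structure(lab, class = "stability_label")
}

stability_levels <- c("unstable_bg_pre", "unstable_bg_post",
                      "unstable_propagation", "stable_propagation")

#' Run one full stimulation trial
#'
#' Builds a fresh random network, equilibrates it, initiates a synchronous
#' pulse of \code{g0} neurons, follows the chain for \code{K_obs} delays
#' plus a post-chain background window, and classifies the outcome.
#' Simulation aborts (spike-rate guard) are recorded as unstable-background
#' labels.
#'
#' @param params a \code{\link{model_params}}.
#' @param mod a \code{\link{dendritic_modulation}}.
#' @param g0 initial pulse size.
#' @param seed integer seed for network and initial condition.
#' @param t_pre pre-stimulus (equilibration/background-check) duration.
#' @param K_obs chain observation horizon in delays.
#' @param t_post post-chain background-check duration.
#' @param f_max,K_min see \code{\link{classify_run}}.
#' @param stim_mode see \code{\link{stim_target_set}}.
#' @param guard_rate spike-rate abort guard (spikes per unit time; default
#'   \code{40 * N} catches runaway synchrony without clipping chains).
#' @param matrix optional pre-built coupling matrix (skips network build).
#' @return list with \code{label}, \code{chain}, \code{bg_pre},
#'   \code{bg_post}, \code{rate} (background rate per neuron), and
#'   \code{seed}.
#' @export
run_trial <- function(params, mod, g0, seed, t_pre = 50, K_obs = 50,
                      t_post = 20, f_max = 0.1, K_min = 20,
                      stim_mode = "random", guard_rate = 40 * params$N,
                      matrix = NULL) {
  set.seed(as.integer(seed))
  if (is.null(matrix)) matrix <- build_network(params, seed = NULL)
  st <- equilibrate(params, matrix, mod, t_eq = t_pre,
                    guard_rate = guard_rate)
  ras_pre <- attr(st, "raster")
  bg_pre <- background_pulses(ras_pre, tol = 1e-9 * params$tau)
  empty_chain <- structure(list(t0 = NA, tau = params$tau, sizes = integer(0),
                                horizon = K_obs, N = params$N),
                           class = "chain")
  if (isTRUE(attr(ras_pre, "aborted"))) {
    return(list(label = structure("unstable_bg_pre",
                                  class = "stability_label"),
                chain = empty_chain, bg_pre = bg_pre, bg_post = NULL,
                rate = NA, seed = seed))
  }
  rate <- nrow(ras_pre) / (params$N * t_pre)
  t0 <- st$t_now + 0.5 * params$tau
  stim <- stimulus_protocol(t0, list(stim_target_set(params$N, g0,
                                                     stim_mode)))
  dur <- (K_obs + 1) * params$tau + t_post
  ras <- simulate_network(params, matrix, mod, duration = dur, stim = stim,
                          state = st, guard_rate = guard_rate)
  if (isTRUE(attr(ras, "aborted"))) {
    return(list(label = structure("unstable_bg_post",
                                  class = "stability_label"),
                chain = empty_chain, bg_pre = bg_pre, bg_post = NULL,
                rate = rate, seed = seed))
  }
  # extract over the whole simulated window so a persistent chain is never
  # double-counted as background in the post-chain check
  horizon_full <- K_obs + ceiling(t_post / params$tau) + 1
  ch <- extract_chain(ras, t0 = t0, tau = params$tau, horizon = horizon_full)
  bg_post <- background_pulses(ras, chain = ch)
  label <- classify_run(ch, bg_pre, bg_post, f_max = f_max, K_min = K_min)
  list(label = label, chain = ch, bg_pre = bg_pre, bg_post = bg_post,
       rate = rate, seed = seed)
}

#' Coupling-strength parameter scan
#'
#' For every combination of mean total excitatory and inhibitory input
#' strengths, rescales the coupling strengths (fixed topology statistics),
#' runs \code{n_nets} independent networks/initial conditions through
#' \code{\link{run_trial}}, and labels the cell by majority vote (ties go to
#' the worst label in the order unstable_bg_pre < unstable_bg_post <
#' unstable_propagation < stable_propagation).
#'
#' @param base a \code{\link{model_params}} template.
#' @param mod a \code{\link{dendritic_modulation}}.
#' @param E_grid,I_grid numeric vectors of total input strengths (I_grid
#'   entries <= 0).
#' @param g0 initial pulse size.
#' @param n_nets networks per grid cell.
#' @param seed master seed; per-trial seeds are derived reproducibly.
#' @param cache_dir optional directory of per-cell completion markers; cells
#'   with an existing marker are loaded, making interrupted scans resumable.
#' @param verbose print per-cell progress lines.
#' @param ... passed to \code{\link{run_trial}} (durations, thresholds).
#' @return a long-format data.frame of class \code{"scan_result"} with one
#'   row per cell: \code{E_tot}, \code{I_tot}, per-label counts and the
#'   majority \code{label}.
#' @export
parameter_scan <- function(base, mod, E_grid, I_grid, g0 = 100, n_nets = 3,
                           seed = 1, cache_dir = NULL, verbose = FALSE,
                           ...) {
  stopifnot(length(E_grid) >= 1, length(I_grid) >= 1, all(I_grid <= 0))
  set.seed(as.integer(seed))
  n_cells <- length(E_grid) * length(I_grid)
  cell_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                  n_cells * n_nets),
                       nrow = n_cells)
  rows <- vector("list", n_cells)
  idx <- 0
  for (E in E_grid) for (I in I_grid) {
    idx <- idx + 1
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("cell_%03d.csv", idx)) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rows[[idx]] <- utils::read.csv(cache_file)
      next
    }
    p <- strengths_from_totals(base, E, I)
    labs <- character(n_nets)
    for (r in seq_len(n_nets)) {
      tr <- run_trial(p, mod, g0 = g0, seed = cell_seeds[idx, r], ...)
      labs[r] <- unclass(tr$label)
    }
    counts <- table(factor(labs, levels = stability_levels))
    best <- max(counts)
    label <- stability_levels[which(counts == best)[1]]  # tie -> worst
    row <- data.frame(E_tot = E, I_tot = I,
                      n_bg_pre = as.integer(counts["unstable_bg_pre"]),
                      n_bg_post = as.integer(counts["unstable_bg_post"]),
                      n_unstable_prop =
                        as.integer(counts["unstable_propagation"]),
                      n_stable = as.integer(counts["stable_propagation"]),
                      label = label)
    if (!is.null(cache_file)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(row, cache_file, row.names = FALSE, quote = FALSE)
    }
    if (verbose)
      message(sprintf("scan cell %d/%d: E=%g I=%g -> %s",
                      idx, n_cells, E, I, label))
    rows[[idx]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", "data.frame")
  attr(out, "g0") <- g0
  attr(out, "n_nets") <- n_nets
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Parameter scan: %d cells, g0 = %s, %s nets/cell\n",
              nrow(x), attr(x, "g0"), attr(x, "n_nets")))
  print(as.data.frame(x))
  invisible(x)
}

#' Largest contiguous block of stable-propagation cells
#'
#' Counts the size of the largest 4-connected component of
#' \code{stable_propagation} cells in a scan result (0 when none).
#'
#' @param scan a \code{\link{parameter_scan}} result.
#' @return integer component size.
#' @export
stable_block_size <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  Es <- sort(unique(scan$E_tot)); Is <- sort(unique(scan$I_tot))
  M <- matrix(FALSE, length(Es), length(Is))
  for (r in seq_len(nrow(scan)))
    M[match(scan$E_tot[r], Es), match(scan$I_tot[r], Is)] <-
      scan$label[r] == "stable_propagation"
  seen <- matrix(FALSE, nrow(M), ncol(M))
  best <- 0L
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (!M[i, j] || seen[i, j]) next
    size <- 0L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        a <- q[1] + d[1]; b <- q[2] + d[2]
        if (a >= 1 && a <= nrow(M) && b >= 1 && b <= ncol(M) &&
            M[a, b] && !seen[a, b]) {
          seen[a, b] <- TRUE
          stack[[length(stack) + 1]] <- c(a, b)
        }
      }
    }
    best <- max(best, size)
  }
  best
}
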