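#' Build a directed Erdős–Rényi coupling matrix
#'
#' Each ordered pair (j, i) of distinct neurons carries a synapse
#' independently with probability \code{p_conn}; conditional on presence the
#' strength is \code{eps_exc} with probability \code{p_exc}, else
#' \code{eps_inh}.  Sign is assigned per connection, not per neuron (no
#' Dale's law).  Self-connections are excluded unless \code{allow_self}.
#'
#' @param params a \code{\link{model_params}}.
#' @param seed integer seed; the realization is reproducible given the seed.
#' @param allow_self include self-connections (default \code{FALSE}).
#' @return an object of class \code{"coupling_matrix"}: an edge list
#'   (\code{pre}, \code{post}, 1-based; \code{w} strengths) plus a compressed
#'   per-sender adjacency used by the simulator.
#' @examples
#' p <- model_params(N = 50, p_conn = 0.2, p_exc = 0.8, eps_exc = 0.01,
#'                   eps_inh = -0.04, I_ext = 1.3)
#' cm <- build_network(p, seed = 1)
#' cm
#' @export
build_network <- function(params, seed, allow_self = FALSE) {
  stopifnot(inherits(params, "model_params"))
  if (!missing(seed) && !is.null(seed)) set.seed(as.integer(seed))
  N <- params$N
  # sample presence per sender column-block to bound memory at large N
  pre <- vector("list", N)
  post <- vector("list", N)
  for (j in seq_len(N)) {
    hit <- which(stats::runif(N) < params$p_conn)
    if (!allow_self) hit <- hit[hit != j]
    pre[[j]] <- rep.int(j, length(hit))
    post[[j]] <- hit
  }
  pre <- unlist(pre); post <- unlist(post)
  w <- ifelse(stats::runif(length(pre)) < params$p_exc,
              params$eps_exc, params$eps_inh)
  new_coupling_matrix(N, pre, post, w,
                      eps_exc = params$eps_exc, eps_inh = params$eps_inh)
}

new_coupling_matrix <- function(N, pre, post, w, eps_exc, eps_inh) {
  ord <- order(pre, post)
  pre <- as.integer(pre[ord]); post <- as.integer(post[ord]); w <- w[ord]
  # CSR over senders: out_ptr[j] .. out_ptr[j+1]-1 are edges out of neuron j
  deg <- tabulate(pre, nbins = N)
  structure(list(N = N, pre = pre, post = post, w = w,
                 out_ptr = c(0L, cumsum(deg)),
                 eps_exc = eps_exc, eps_inh = eps_inh),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  ne <- sum(x$w > 0); ni <- sum(x$w < 0)
  cat(sprintf("Coupling matrix: N = %d, %d synapses (%d exc, %d inh)\n",
              x$N, length(x$w), ne, ni))
  cat(sprintf("  mean out-degree %.2f; strengths %g / %g\n",
              length(x$w) / x$N, x$eps_exc, x$eps_inh))
  invisible(x)
}

#' @export
summary.coupling_matrix <- function(object, ...) {
  indeg <- tabulate(object$post, nbins = object$N)
  outdeg <- diff(object$out_ptr)
  list(N = object$N, n_edges = length(object$w),
       n_exc = sum(object$w > 0), n_inh = sum(object$w < 0),
       in_degree = summary(indeg), out_degree = summary(outdeg))
}

#' @export
as.data.frame.coupling_matrix <- function(x, ...) {
  data.frame(pre = x$pre, post = x$post, w = x$w)
}

#' Write / read a coupling matrix as 3-column CSV
#'
#' Columns \code{pre_id}, \code{post_id}, \code{strength} with 0-based
#' neuron indices.
#'
#' @param x a \code{coupling_matrix}.
#' @param file path to a CSV file.
#' @param N network size (needed on read because isolated neurons carry no
#'   rows); defaults to \code{max(index) + 1}.
#' @export
write_coupling_csv <- function(x, file) {
  stopifnot(inherits(x, "coupling_matrix"))
  utils::write.csv(data.frame(pre_id = x$pre - 1L, post_id = x$post - 1L,
                              strength = x$w),
                   file, row.names = FALSE, quote = FALSE)
}

#' @rdname write_coupling_csv
#' @export
read_coupling_csv <- function(file, N = NULL) {
  d <- utils::read.csv(file)
  stopifnot(all(c("pre_id", "post_id", "strength") %in% names(d)))
  if (is.null(N)) N <- max(d$pre_id, d$post_id) + 1L
  ee <- max(c(d$strength[d$strength > 0], 0))
  ei <- min(c(d$strength[d$strength < 0], 0))
  new_coupling_matrix(as.integer(N), d$pre_id + 1L, d$post_id + 1L,
                      d$strength, eps_exc = ee, eps_inh = ei)
}
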