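# Shared small parameter sets and builders for the test suite.

# a desk-scale network in the same dynamical regime as the shipped fixtures
small_params <- function(N = 300, I_ext = 1.25, eps_exc = 0.01,
                         eps_inh = -0.035, p_conn = 0.05, p_exc = 0.8) {
  model_params(N = N, p_conn = p_conn, p_exc = p_exc, eps_exc = eps_exc,
               eps_inh = eps_inh, I_ext = I_ext)
}

lin_mod <- function() dendritic_modulation(linear = TRUE)

# an empty coupling matrix (no synapses) for closed-form checks
empty_matrix <- function(N) {
  dendsyn:::new_coupling_matrix(N, integer(0), integer(0), numeric(0),
                                eps_exc = 1e-9, eps_inh = 0)
}

# build a raster directly (planted fixtures)
planted_raster <- function(time, neuron, tag = 0L, N = max(neuron)) {
  dendsyn:::new_spike_raster(time, neuron, rep_len(tag, length(time)), N)
}

# uniform potential density on (0, 1): F(lam) = lam analytically
uniform_density <- function(params) {
  grid <- seq(0, 1, length.out = 2001)
  dendsyn:::new_stationary_density(grid, rep(1, 2001), rate_nu = NA,
                                   source = "empirical", params = params)
}
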