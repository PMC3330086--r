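test_that("self-consistent rate reduces to 1/T_free without coupling and is
           monotone in inhibition", {
  p0 <- model_params(N = 200, p_conn = 0.05, p_exc = 0.8, eps_exc = 1e-12,
                     eps_inh = 0, I_ext = 2)
  p0$eps_exc <- 0
  expect_equal(self_consistent_rate(p0, lin_mod()), 1 / free_period(p0))
  nus <- vapply(c(-0.01, -0.03, -0.06, -0.1), function(ei) {
    p <- small_params(N = 500, eps_inh = ei)
    self_consistent_rate(p, lin_mod())
  }, numeric(1))
  expect_true(all(diff(nus) <= 1e-9))
})

test_that("diffusion density is normalized, vanishes at threshold, and has
           the deterministic-occupancy limit", {
  p <- small_params(N = 500)
  nu <- self_consistent_rate(p, lin_mod())
  d <- stationary_density_diffusion(p, nu)
  tr <- sum(diff(d$grid) * (d$density[-1] + d$density[-length(d$density)]) / 2)
  expect_equal(tr, 1, tolerance = 1e-6)
  expect_equal(d$density[length(d$density)], 0)
  # sigma_w -> 0: density approaches 1 / (T_free (I - gamma V)) on (Vr, Vt)
  pw <- small_params(N = 500, eps_exc = 1e-5, eps_inh = -3.5e-5)
  nu_w <- self_consistent_rate(pw, lin_mod())
  dw <- stationary_density_diffusion(pw, nu_w)
  Tf <- free_period(pw)
  sel <- dw$grid > 0.1 & dw$grid < 0.9
  expect_equal(dw$density[sel],
               1 / (Tf * (pw$I_ext - pw$gamma * dw$grid[sel])),
               tolerance = 1e-3)
  # exact degenerate branch
  p0 <- small_params(N = 500)
  p0$eps_exc <- 0; p0$eps_inh <- 0
  d0 <- stationary_density_diffusion(p0, 1 / free_period(p0))
  expect_equal(d0$density[1000],
               1 / (free_period(p0) * (p0$I_ext - p0$gamma * d0$grid[1000])),
               tolerance = 1e-6)
})

test_that("empirical density converges to the sampling density", {
  p <- small_params(N = 500)
  set.seed(1)
  x <- runif(5e4)  # uniform potentials on (0, 1)
  d <- suppressWarnings(empirical_density(x, p))
  expect_equal(excitation_probability(0.25, d), 0.25, tolerance = 0.02)
  # point mass lands in one bin
  dp <- suppressWarnings(empirical_density(rep(0.5, 2e4), p))
  expect_equal(sum(dp$density > 0), 1)
  # KS distance to the true cdf shrinks with sample size
  ks <- vapply(c(1e3, 1e4, 1e5), function(n) {
    set.seed(2)
    dd <- suppressWarnings(empirical_density(runif(n), p))
    gr <- seq(0.05, 0.95, by = 0.05)
    max(abs(vapply(gr, function(v) dd$Fright(v), numeric(1)) - (1 - gr)))
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
})

test_that("excitation probability is the right-cumulative of the density", {
  p <- small_params()
  d <- uniform_density(p)
  expect_equal(excitation_probability(0, d), 0)
  expect_equal(excitation_probability(-0.3, d), 0)
  expect_equal(excitation_probability(0.25, d), 0.25, tolerance = 1e-6)
  expect_equal(excitation_probability(1.7, d), 1)
  lam <- seq(-0.5, 1.5, length.out = 200)
  expect_true(all(diff(excitation_probability(lam, d)) >= -1e-12))
})

test_that("group input distribution is the stated trinomial", {
  p <- small_params(N = 300, p_conn = 0.1, p_exc = 0.8)
  g0 <- group_input_distribution(0, p)
  expect_equal(dim(g0$P), c(1, 1))
  expect_equal(g0$P[1, 1], 1)
  g1 <- group_input_distribution(1, p)
  expect_equal(g1$P[cbind(2, 1)], 0.08, tolerance = 1e-12)
  expect_equal(g1$P[cbind(1, 2)], 0.02, tolerance = 1e-12)
  expect_equal(g1$P[1, 1], 0.90, tolerance = 1e-12)
  # g = 50: Monte-Carlo link sampling within 4 sigma
  gd <- group_input_distribution(50, p)
  expect_equal(sum(gd$P), 1, tolerance = 1e-12)
  set.seed(3)
  n <- 4e4
  draws <- rmultinom(n, 50, c(0.08, 0.02, 0.90))
  p_m2 <- mean(draws[1, ] == 2)
  th <- sum(gd$P[gd$m == 2, ])
  expect_lt(abs(p_m2 - th), 4 * sqrt(th * (1 - th) / n))
  # truncated window keeps essentially all mass
  gd_big <- group_input_distribution(250, p, window_sd = 8)
  expect_equal(sum(gd_big$P), 1, tolerance = 1e-8)
})

test_that("spike response probability reduces to F on degenerate topology and
           is amplified by the nonlinearity", {
  p <- model_params(N = 50, p_conn = 1, p_exc = 1, eps_exc = 0.01,
                    eps_inh = -1e-9, I_ext = 1.25)
  d <- uniform_density(p)
  g <- c(5, 20, 40)
  expect_equal(spike_response_probability(g, p, lin_mod(), d),
               excitation_probability(g * 0.01, d), tolerance = 1e-9)
  # supra-additive modulation strictly increases p(g) in its active range
  ps <- small_params(N = 400)
  dn <- stationary_density_diffusion(ps, self_consistent_rate(ps, lin_mod()))
  mod <- dendritic_modulation(theta_b = 0.03, theta_s = 0.06, s_sat = 0.3)
  g2 <- c(60, 100, 150)
  expect_true(all(spike_response_probability(g2, ps, mod, dn) >
                    spike_response_probability(g2, ps, lin_mod(), dn)))
  expect_equal(spike_response_probability(0, ps, mod, dn), 0)
})

test_that("transition pmf is binomial: normalization, mean identity, and
           exhaustive enumeration at tiny N", {
  p <- small_params(N = 20)
  d <- uniform_density(p)
  tm <- transition_model(p, lin_mod(), d)
  for (g in c(0, 5, 13, 20)) {
    pmf <- transition_pmf(tm, g)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_equal(sum((0:(20 - g)) * pmf), tm$E_hat[match(g, tm$g)],
                 tolerance = 1e-10)
  }
  # brute-force enumeration over all 2^(N-g) i.i.d. threshold outcomes
  g <- 14; n_avail <- 6
  pg <- tm$p_g[match(g, tm$g)]
  brute <- numeric(n_avail + 1)
  for (mask in 0:(2^n_avail - 1)) {
    k <- sum(bitwAnd(mask, 2^(0:(n_avail - 1))) > 0)
    brute[k + 1] <- brute[k + 1] + pg^k * (1 - pg)^(n_avail - k)
  }
  expect_equal(transition_pmf(tm, g), brute, tolerance = 1e-12)
  # sampling honours the seed and the mean
  s1 <- sample_transition(tm, 10, 500, seed = 7)
  s2 <- sample_transition(tm, 10, 500, seed = 7)
  expect_identical(s1, s2)
})

test_that("expectation curve endpoints and pmf-mean consistency hold", {
  p <- small_params(N = 150)
  d <- stationary_density_diffusion(p, self_consistent_rate(p, lin_mod()))
  tm <- transition_model(p, lin_mod(), d)
  ec <- expectation_curve(tm)
  expect_equal(ec$E_hat[1], 0)
  expect_equal(ec$E_hat[151], 0)  # g = N: empty available pool
  expect_equal(ec$E_hat, (150 - ec$g) * ec$p_g)
  # monotone coupling: p(g) non-decreasing in g before saturation
  expect_true(all(diff(ec$p_g[1:50]) >= -1e-12))
})

test_that("per-network exact response probability matches the mean-field one
           on average", {
  p <- small_params(N = 200)
  d <- stationary_density_diffusion(p, self_consistent_rate(p, lin_mod()))
  mod <- dendritic_modulation(theta_b = 0.03, theta_s = 0.06, s_sat = 0.3)
  set.seed(5)
  phat <- mean(vapply(1:8, function(s) {
    cm <- build_network(p, seed = s)
    network_response_probability(cm, 50, p, mod, d)
  }, numeric(1)))
  pmf <- spike_response_probability(50, p, mod, d)
  expect_equal(phat, pmf, tolerance = 0.15)
})
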