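test_that("dendritic modulation is piecewise linear with continuous knots", {
  m <- dendritic_modulation(theta_b = 2, theta_s = 4, s_sat = 6)
  expect_equal(sigma_modulate(1.0, m), 1.0)    # identity region
  expect_equal(sigma_modulate(3.0, m), 4.0)    # affine interpolation
  expect_equal(sigma_modulate(9.0, m), 6.0)    # saturation plateau
  # continuity at both knots
  expect_equal(sigma_modulate(2, m), sigma_modulate(2 + 1e-12, m),
               tolerance = 1e-9)
  expect_equal(sigma_modulate(4 - 1e-12, m), 6, tolerance = 1e-9)
  # linear mode is the identity
  lin <- lin_mod()
  expect_equal(sigma_modulate(0.37, lin), 0.37)
  x <- runif(1e4, 0, 50)
  expect_identical(sigma_modulate(x, lin), x)
  # negative input is a domain error (inhibition never passes through)
  expect_error(sigma_modulate(-0.1, m), "negative")
})

test_that("supra-additivity then saturation: sigma >= x up to s_sat, <= x beyond", {
  m <- dendritic_modulation(theta_b = 1, theta_s = 3, s_sat = 5)
  x1 <- seq(1, 5, length.out = 200)
  expect_true(all(sigma_modulate(x1, m) >= x1 - 1e-12))
  x2 <- seq(5, 20, length.out = 200)
  expect_true(all(sigma_modulate(x2, m) <= x2 + 1e-12))
  # non-decreasing everywhere
  x <- sort(runif(1000, 0, 10))
  expect_true(all(diff(sigma_modulate(x, m)) >= -1e-12))
})

test_that("model_params validates its invariants", {
  expect_error(model_params(N = 100, p_conn = 0.1, p_exc = 0.7, p_inh = 0.2,
                            eps_exc = 0.01, eps_inh = -0.04, I_ext = 2),
               "p_exc")
  expect_error(model_params(N = 100, p_conn = 0.1, p_exc = 0.8,
                            eps_exc = 0.01, eps_inh = -0.04, I_ext = 0.9),
               "supra-threshold")
  expect_error(model_params(N = 100, p_conn = 0.1, p_exc = 0.8,
                            eps_exc = 0.01, eps_inh = 0.04, I_ext = 2))
})

test_that("mean total input strengths and their inverse round-trip", {
  p <- model_params(N = 1000, p_conn = 0.1, p_exc = 0.8, eps_exc = 0.01,
                    eps_inh = -0.02, I_ext = 2)
  tot <- mean_total_input_strengths(p)
  expect_equal(unname(tot["E_tot"]), 0.8)
  expect_equal(unname(tot["I_tot"]), 1000 * 0.1 * 0.2 * -0.02)
  p2 <- strengths_from_totals(p, tot[["E_tot"]], tot[["I_tot"]])
  expect_equal(p2$eps_exc, p$eps_exc, tolerance = 1e-12)
  expect_equal(p2$eps_inh, p$eps_inh, tolerance = 1e-12)
})

test_that("network construction matches its sampling law", {
  p <- small_params(N = 60, p_conn = 0.2)
  # degenerate cases
  p1 <- p; p1$p_conn <- 1; p1$p_exc <- 1; p1$p_inh <- 0
  cm1 <- build_network(p1, seed = 1)
  expect_equal(length(cm1$w), 60 * 59)
  expect_true(all(cm1$w == p1$eps_exc))
  expect_true(all(cm1$pre != cm1$post))  # no self-connections
  # edge counts and sign fractions within 4 sigma over 100 seeds
  n_edges <- n_exc <- numeric(100)
  for (s in 1:100) {
    cm <- build_network(p, seed = s)
    n_edges[s] <- length(cm$w)
    n_exc[s] <- sum(cm$w > 0)
  }
  n_pairs <- 60 * 59 * 100
  expect_lt(abs(sum(n_edges) - n_pairs * 0.2),
            4 * sqrt(n_pairs * 0.2 * 0.8))
  expect_lt(abs(sum(n_exc) - sum(n_edges) * 0.8),
            4 * sqrt(sum(n_edges) * 0.8 * 0.2))
  # reproducibility
  expect_identical(build_network(p, seed = 7), build_network(p, seed = 7))
})

test_that("coupling matrix CSV round-trips with 0-based indices", {
  p <- small_params(N = 40, p_conn = 0.2)
  cm <- build_network(p, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_coupling_csv(cm, f)
  d <- read.csv(f)
  expect_named(d, c("pre_id", "post_id", "strength"))
  expect_equal(min(d$pre_id), 0)
  cm2 <- read_coupling_csv(f, N = 40)
  expect_equal(cm2$pre, cm$pre)
  expect_equal(cm2$post, cm$post)
  expect_equal(cm2$w, cm$w)
  unlink(f)
})
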