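test_that("uncoupled neurons spike periodically at the free period", {
  p <- model_params(N = 20, p_conn = 0.5, p_exc = 1, eps_exc = 1e-9,
                    eps_inh = 0, I_ext = 2)
  r <- simulate_network(p, empty_matrix(20), lin_mod(), duration = 6,
                        seed = 11)
  isis <- unlist(tapply(r$time, r$neuron, diff))
  expect_gt(length(isis), 100)
  expect_lt(max(abs(isis - free_period(p)) / free_period(p)), 1e-9)
})

test_that("stimulus pulses force spikes at exactly the pulse time", {
  p <- small_params(N = 50)
  cm <- build_network(p, seed = 5)
  stim <- stimulus_protocol(1.25, list(1:10))
  r <- simulate_network(p, cm, lin_mod(), duration = 3, stim = stim,
                        seed = 6)
  hit <- r[r$time == 1.25, ]
  expect_setequal(hit$neuron[hit$tag == "stimulus"], 1:10)
})

test_that("identical seeds give bit-identical rasters and states", {
  p <- small_params(N = 80)
  cm <- build_network(p, seed = 2)
  r1 <- simulate_network(p, cm, lin_mod(), duration = 15, seed = 9)
  r2 <- simulate_network(p, cm, lin_mod(), duration = 15, seed = 9)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "state"), attr(r2, "state"))
})

test_that("equilibrate honors t_eq = 0 and is seed-deterministic", {
  p <- small_params(N = 60)
  cm <- build_network(p, seed = 1)
  s0 <- equilibrate(p, cm, lin_mod(), t_eq = 0, seed = 4)
  expect_equal(s0$t_now, 0)
  expect_true(all(s0$phases >= 0 & s0$phases < free_period(p)))
  expect_equal(nrow(s0$transit), round(60 * p$p_conn))
  expect_true(all(s0$transit$dt >= 0 & s0$transit$dt < p$tau))
  s1 <- equilibrate(p, cm, lin_mod(), t_eq = 10, seed = 4)
  s2 <- equilibrate(p, cm, lin_mod(), t_eq = 10, seed = 4)
  expect_identical(s1$phases, s2$phases)
  expect_identical(s1$transit, s2$transit)
})

test_that("delayed delivery is causal: responses follow senders by tau", {
  # two neurons, single strong excitatory synapse 1 -> 2
  p <- model_params(N = 2, p_conn = 0.5, p_exc = 1, eps_exc = 0.9,
                    eps_inh = 0, I_ext = 2, tau = 0.13)
  cm <- dendsyn:::new_coupling_matrix(2, 1L, 2L, 0.9, 0.9, 0)
  st <- dendsyn:::new_sim_state(c(free_period(p) * 0.999999, 0.0),
                                numeric(0), integer(0))
  r <- dendsyn:::run_segment(st, p, cm, lin_mod(), duration = 0.5)$raster
  # wave-triggered responses of neuron 2 must occur exactly tau after a
  # sender spike of neuron 1
  wave_resp <- r$time[r$neuron == 2]
  sender <- r$time[r$neuron == 1]
  trig <- wave_resp[vapply(wave_resp, function(t)
    any(abs(sender + p$tau - t) < 1e-9 * p$tau), logical(1))]
  expect_gt(length(trig), 0)
})

test_that("spike delivery count equals sender out-degree", {
  # one sender wired to 3 targets with supra-threshold strength: one spike
  # from the sender must fire all 3 targets simultaneously tau later
  p <- model_params(N = 5, p_conn = 0.5, p_exc = 1, eps_exc = 1.2,
                    eps_inh = 0, I_ext = 2, tau = 0.1)
  cm <- dendsyn:::new_coupling_matrix(5, c(1L, 1L, 1L), c(2L, 3L, 4L),
                                      rep(1.2, 3), 1.2, 0)
  st <- dendsyn:::new_sim_state(rep(0, 5), numeric(0), integer(0))
  stim <- stimulus_protocol(0.05, list(1L))
  r <- dendsyn:::run_segment(st, p, cm, lin_mod(), duration = 0.2,
                             stim = stim)$raster
  resp <- r[abs(r$time - 0.15) < 1e-10, ]
  expect_setequal(resp$neuron, 2:4)
})

test_that("the rate guard aborts runaway activity with a diagnostic", {
  # all-to-all strong excitation: one stimulus ignites the whole network
  p <- model_params(N = 40, p_conn = 1, p_exc = 1, eps_exc = 1.5,
                    eps_inh = 0, I_ext = 2, tau = 0.01)
  cm <- build_network(p, seed = 1)
  stim <- stimulus_protocol(0.1, list(1:40))
  r <- simulate_network(p, cm, lin_mod(), duration = 50, stim = stim,
                        seed = 1, guard_rate = 500)
  expect_true(attr(r, "aborted"))
  expect_match(attr(r, "abort_reason"), "guard")
})

test_that("background mean rate matches the self-consistent theory within 10%", {
  p <- small_params(N = 400)
  cm <- build_network(p, seed = 21)
  st <- equilibrate(p, cm, lin_mod(), t_eq = 10, seed = 22)
  seg <- dendsyn:::run_segment(st, p, cm, lin_mod(), duration = 30)
  rate_sim <- nrow(seg$raster) / (400 * 30)
  rate_th <- self_consistent_rate(p, lin_mod())
  expect_lt(abs(rate_sim - rate_th) / rate_th, 0.10)
})

test_that("membrane-potential distribution is stationary after equilibration", {
  p <- small_params(N = 300)
  cm <- build_network(p, seed = 31)
  set.seed(32)
  st <- equilibrate(p, cm, lin_mod(), t_eq = 30)
  v1 <- v2 <- numeric(0)
  for (k in 1:10) {
    st <- dendsyn:::run_segment(st, p, cm, lin_mod(), duration = 1)$state
    v1 <- c(v1, membrane_potentials(st, p))
  }
  for (k in 1:10) {
    st <- dendsyn:::run_segment(st, p, cm, lin_mod(), duration = 1)$state
    v2 <- c(v2, membrane_potentials(st, p))
  }
  d <- suppressWarnings(ks.test(v1, v2)$statistic)
  expect_lt(unname(d), 0.05)
})

test_that("raster CSV round-trips", {
  p <- small_params(N = 30)
  cm <- build_network(p, seed = 2)
  r <- simulate_network(p, cm, lin_mod(), duration = 5, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_raster_csv(r, f)
  r2 <- read_raster_csv(f)
  expect_equal(r2$time, r$time)
  expect_equal(r2$neuron, r$neuron)
  expect_equal(attr(r2, "N"), 30)
  unlink(f)
})
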