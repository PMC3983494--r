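test_that("continuous-limit likelihood has the closed form for constant intensity", {
  # uncoupled, non-adapting neuron: rho is constant at rho0 e^{-theta/du}
  p0 <- neuron_params(eta0 = 0)
  B <- 25
  net <- dual_network(1, 0, params = p0, w_g = matrix(0, 1, 1),
                      w_q = matrix(0, 1, 1))
  rho <- firing_intensity(0, p0)

  silent <- run_network(net, "learn", clamp = spike_raster(matrix(0L, 1, B)))
  expect_equal(complete_log_likelihood(silent, "G"), -rho * B * p0$dt)

  one <- matrix(0L, 1, B); one[1, 7] <- 1L
  tr_one <- run_network(net, "learn", clamp = spike_raster(one))
  expect_equal(complete_log_likelihood(tr_one, "G"), log(rho) - rho * B * p0$dt)
})

test_that("the two likelihood forms agree to first order in rho dt", {
  p_small <- neuron_params(dt = 0.01)
  net <- dual_network(2, 0, params = p_small, seed = 2)
  clamp <- poisson_raster(c(0.3, 0.3), 50, dt = 0.01, seed = 3)
  tr <- run_network(net, "learn", clamp = clamp)
  cont <- complete_log_likelihood(tr, "G", form = "continuous_limit")
  disc <- complete_log_likelihood(tr, "G", form = "discrete_exact")
  # discrete log P = continuous density + K log dt + O(rho dt) corrections
  K <- sum(clamp$spikes)
  expect_lt(abs((disc - K * log(p_small$dt)) - cont), 0.02 * abs(cont))
})

test_that("discrete-exact probabilities normalize over all rasters", {
  # every raster of a recurrent 2-neuron, 3-bin network
  net <- dual_network(2, 0, seed = 4, init_sd = 0.5)
  total <- 0
  for (r in all_rasters(2, 3)) {
    tr <- spikevar:::trace_given_raster(net, spike_raster(r))
    total <- total + exp(complete_log_likelihood(tr, "G", form = "discrete_exact"))
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("Q-likelihood is defined on hidden neurons only", {
  net <- tiny_net(2, 2)
  tr <- run_network(net, "learn", clamp = tiny_clamp(2, 5), seed = 1)
  expect_error(complete_log_likelihood(tr, "Q", neurons = 1:2), "visible")
  expect_silent(complete_log_likelihood(tr, "Q"))
})

test_that("simplified free energy ignores hidden activity", {
  net <- tiny_net(2, 2, seed = 5)
  clamp <- tiny_clamp(2, 10)
  a <- run_network(net, "learn", clamp = clamp, seed = 1)
  b <- run_network(net, "learn", clamp = clamp, seed = 99) # other hidden spikes
  expect_false(identical(a$raster$spikes, b$raster$spikes))
  # visible intensities at bin t depend on hidden history, so compare on a
  # network whose visible neurons receive no hidden input
  net2 <- net
  net2$w_g[1:2, 3:4] <- 0
  a2 <- run_network(net2, "learn", clamp = clamp, seed = 1)
  b2 <- run_network(net2, "learn", clamp = clamp, seed = 99)
  expect_equal(instantaneous_free_energy(a2, "simplified"),
               instantaneous_free_energy(b2, "simplified"))
})

test_that("full equals simplified free energy when recognition weights are tied", {
  net <- tie_recognition_weights(tiny_net(2, 3, seed = 6, init_sd = 0.2))
  tr <- run_network(net, "learn", clamp = tiny_clamp(2, 20), seed = 2)
  expect_equal(instantaneous_free_energy(tr, "full"),
               instantaneous_free_energy(tr, "simplified"), tolerance = 1e-12)
})

test_that("free energy rejects generative samples", {
  net <- tiny_net(2, 1)
  tr <- run_network(net, "generate", 10, seed = 1)
  expect_error(instantaneous_free_energy(tr), "clamped")
})

test_that("expected free energy upper-bounds the negative data log-likelihood", {
  # enumeration oracle: <F>_q + log p(X_V) = KL(q || posterior) >= 0
  for (seed in 1:4) {
    net <- tiny_net(2, 2, seed = seed, init_sd = 0.3)
    clamp <- tiny_clamp(2, 3, seed = seed + 10)
    om <- oracle_marginal(enumeration_oracle(2, 3, clamp), net)
    gap <- om$expected_free_energy + om$log_p_visible
    expect_gte(gap, -1e-10)
    expect_equal(gap, om$kl, tolerance = 1e-10)
    expect_equal(sum(om$posterior), 1, tolerance = 1e-12)
    expect_equal(sum(om$q_prob), 1, tolerance = 1e-12)
  }
})

test_that("novelty tracker converges, responds to steps, and freezes with an infinite baseline", {
  # constant input from explicit cold start: e_N -> 0 geometrically
  tk <- fe_tracker(tau_g = 10, tau_baseline = 100, fast_init = 0, slow_init = 0)
  c0 <- 3
  en <- numeric(2000)
  for (t in 1:2000) {
    st <- update_novelty(tk, c0, dt = 1)
    tk <- st$tracker
    en[t] <- st$e_n
  }
  # geometric decay: residual shrinks by ~e^{-1} per slow time constant
  expect_lt(abs(en[500]), abs(en[200]) * exp(-2))
  expect_lt(abs(en[2000]), 1e-6)
  expect_equal(tk$fast_avg, c0, tolerance = 1e-8)
  expect_equal(tk$slow_baseline, c0, tolerance = 1e-6)

  # step change c -> c': closed-form two-exponential response
  a <- 1 / 10; b <- 1 / 100
  tk2 <- fe_tracker(10, 100, fast_init = c0, slow_init = c0)
  step <- 5
  fast <- c0; slow <- c0
  for (t in 1:30) {
    st <- update_novelty(tk2, step, dt = 1)
    tk2 <- st$tracker
    fast <- fast + a * (step - fast)
    slow <- slow + b * (fast - slow)
    expect_equal(st$e_n, fast - slow, tolerance = 1e-12)
  }
  expect_gt(tk2$fast_avg - tk2$slow_baseline, 0) # transient proportional to c' - c

  # tau_baseline -> infinity: baseline frozen, e_N -> c' - baseline
  tk3 <- fe_tracker(10, 1e12, fast_init = c0, slow_init = c0)
  for (t in 1:2000) tk3 <- update_novelty(tk3, step, dt = 1)$tracker
  expect_equal(tk3$slow_baseline, c0, tolerance = 1e-6)
  expect_equal(tk3$fast_avg - tk3$slow_baseline, step - c0, tolerance = 1e-6)

  # default NA start: first observation initializes both averages
  tk4 <- fe_tracker()
  st <- update_novelty(tk4, 7, dt = 1)
  expect_equal(st$e_n, 0)
  expect_equal(st$tracker$fast_avg, 7)
})

test_that("novelty signal averages to zero on a long stationary run", {
  set.seed(9)
  f <- rnorm(20000, mean = 4, sd = 1)
  nt <- novelty_trace(f, fe_tracker(fast_init = 4, slow_init = 4), dt = 1)
  expect_lt(abs(mean(nt$e_n)), 3 / sqrt(20000) * 10)
  expect_equal(nt$e_n, nt$fast_avg - nt$slow_baseline)
})

test_that("novelty traces export as TSV", {
  nt <- novelty_trace(c(1, 2, 3), fe_tracker(), dt = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fe_tsv(nt, path)
  back <- read.delim(path)
  expect_equal(back$e_n, nt$e_n)
  expect_equal(names(back),
               c("bin", "time_ms", "f_instant", "fast_avg", "slow_baseline", "e_n"))
})
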