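test_that("trace propagation is the exact exponential filter", {
  expect_equal(decay_and_increment(0, 1, dt = 1, tau = 10), 1.0)
  expect_equal(decay_and_increment(1, 0, dt = 1, tau = 10), exp(-0.1))
  expect_equal(decay_and_increment(0, 0, dt = 1, tau = 10), 0)
  expect_error(decay_and_increment(0, 0, dt = -1, tau = 10), "dt")
  expect_error(decay_and_increment(0, 0, dt = 1, tau = 0), "tau")

  # trace equals the analytic convolution sum over spike times
  set.seed(11)
  p <- neuron_params()
  for (rep in 1:5) {
    spikes <- rbinom(40, 1, 0.3)
    phi <- 0
    for (t in seq_along(spikes)) {
      # value *before* the bin's spike is applied: a spike in bin s enters
      # with unit amplitude and has decayed (t - 1 - s) steps by bin t
      past <- which(spikes[seq_len(t - 1)] == 1)
      analytic <- sum(exp(-(t - 1 - past) * p$dt / p$tau))
      expect_equal(phi, analytic, tolerance = 1e-12)
      phi <- decay_and_increment(phi, spikes[t], p$dt, p$tau)
    }
  }
})

test_that("adaptation potential decays and steps by -eta0", {
  p <- neuron_params()
  expect_equal(adaptation_step(0, 1, p), -0.1)
  expect_equal(adaptation_step(-0.1, 0, p), -0.1 * exp(-0.1))
  expect_equal(adaptation_step(0, 0, p), 0)
  # never positive when started from rest
  eta <- 0
  set.seed(2)
  for (t in 1:100) {
    eta <- adaptation_step(eta, rbinom(1, 1, 0.5), p)
    expect_lte(eta, 0)
  }
})

test_that("membrane potential sums weighted traces plus adaptation", {
  expect_equal(membrane_potential(rep(0, 3), runif(3), -0.1), -0.1)
  expect_equal(membrane_potential(1.0, 0.5, 0), 0.5)
  set.seed(3)
  w <- rnorm(7); phi <- runif(7); eta <- rnorm(1)
  expect_equal(membrane_potential(w, phi, eta),
               sum(vapply(1:7, function(j) w[j] * phi[j], 0)) + eta)
  expect_error(membrane_potential(1:2, 1:3, 0), "length")
})

test_that("escape rate is exponential in the potential and guarded", {
  p <- neuron_params()
  expect_equal(firing_intensity(p$theta, p), p$rho0)
  expect_equal(firing_intensity(p$theta + p$delta_u, p), p$rho0 * exp(1))
  expect_equal(firing_intensity(-1e6, p), 0, tolerance = 1e-200)
  expect_true(is.finite(firing_intensity(1e6, p)))
  u <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(firing_intensity(u, p)) > 0))
})

test_that("finite-bin spike probability matches the Poisson closed form", {
  expect_equal(spike_probability(0, 1), 0)
  expect_equal(spike_probability(0.7, 1), 1 - exp(-0.7))
  expect_equal(spike_probability(0.001, 1), 1 - exp(-0.001))
  expect_lt(abs(spike_probability(0.001, 1) - 0.001), 1e-6) # ~ rho dt
  expect_error(spike_probability(-0.1, 1), "non-negative")
})

test_that("clamped visible spikes are bit-identical to the data", {
  net <- tiny_net(3, 2, seed = 4)
  clamp <- tiny_clamp(3, 50, rate = 0.3, seed = 6)
  for (mode in c("learn", "infer")) {
    tr <- run_network(net, mode, clamp = clamp, seed = 9)
    expect_identical(tr$raster$spikes[1:3, ], clamp$spikes)
  }
})

test_that("run_network mode contracts are enforced", {
  net <- tiny_net(2, 1)
  clamp <- tiny_clamp(2, 5)
  expect_error(run_network(net, "generate", 10, clamp = clamp), "clamp")
  expect_error(run_network(net, "learn", 10), "clamp")
  expect_error(run_network(net, "learn", clamp = tiny_clamp(3, 5)), "visible")
  expect_error(run_network(net, "generate", 0), "positive")
})

test_that("identical seeds give identical traces", {
  net <- tiny_net(3, 3, seed = 8)
  a <- run_network(net, "generate", 100, seed = 123)
  b <- run_network(net, "generate", 100, seed = 123)
  expect_identical(a$raster$spikes, b$raster$spikes)
  expect_identical(a$rho_g, b$rho_g)
  clamp <- tiny_clamp(3, 100)
  a <- run_network(net, "learn", clamp = clamp, seed = 42)
  b <- run_network(net, "learn", clamp = clamp, seed = 42)
  expect_identical(a$raster$spikes, b$raster$spikes)
})

test_that("dynamics are causal: a late data change never affects the past", {
  net <- tiny_net(2, 2, seed = 10)
  clamp1 <- tiny_clamp(2, 30, seed = 20)
  spikes2 <- clamp1$spikes
  t_chg <- 20L
  spikes2[, t_chg:30] <- 1L - spikes2[, t_chg:30]
  clamp2 <- spike_raster(spikes2)
  a <- run_network(net, "learn", clamp = clamp1, seed = 7)
  b <- run_network(net, "learn", clamp = clamp2, seed = 7)
  pre <- seq_len(t_chg - 1L)
  expect_identical(a$raster$spikes[, pre], b$raster$spikes[, pre])
  # potentials and intensities at the change bin itself are still computed
  # from pre-change history
  upto <- seq_len(t_chg)
  expect_equal(a$phi[, upto], b$phi[, upto])
  expect_equal(a$eta[, upto], b$eta[, upto])
  expect_equal(a$u_g[, upto], b$u_g[, upto])
  expect_equal(a$rho_q[, upto], b$rho_q[, upto])
})

test_that("potentials are consistent with traces and weights bin by bin", {
  net <- tiny_net(2, 2, seed = 12)
  tr <- run_network(net, "learn", clamp = tiny_clamp(2, 20), seed = 3)
  for (t in c(1, 7, 20)) {
    u <- as.vector(net$w_g %*% tr$phi[, t]) + tr$eta[, t]
    expect_equal(tr$u_g[, t], u)
    expect_equal(tr$rho_g[, t], firing_intensity(u, net$params))
  }
  expect_true(all(tr$phi >= 0))
  expect_true(all(tr$rho_g > 0))
  expect_true(all(tr$rho_q > 0))
})

test_that("uncoupled non-adapting neurons spike as i.i.d. Bernoulli bins", {
  # with eta0 = 0 and zero weights the per-bin spike probability is
  # 1 - exp(-dt rho0 e^{-theta/delta_u}) and counts are Binomial
  p0 <- neuron_params(eta0 = 0)
  n <- 4; B <- 4000
  net <- dual_network(n, 0, params = p0,
                      w_g = matrix(0, n, n), w_q = matrix(0, n, n))
  tr <- run_network(net, "generate", B, seed = 77)
  p_bin <- spike_probability(firing_intensity(0, p0), p0$dt)
  for (i in seq_len(n)) {
    pv <- binom.test(sum(tr$raster$spikes[i, ]), B, p_bin)$p.value
    expect_gt(pv, 0.001)
  }
  # inference mode with zero recognition input: hidden neurons likewise
  net2 <- dual_network(1, 3, params = p0, init_sd = 0)
  clamp <- spike_raster(matrix(0L, 1, B))
  tr2 <- run_network(net2, "infer", clamp = clamp, seed = 78)
  for (i in 2:4) {
    pv <- binom.test(sum(tr2$raster$spikes[i, ]), B, p_bin)$p.value
    expect_gt(pv, 0.001)
  }
})

test_that("trace state carries over between consecutive windows on request", {
  net <- tiny_net(2, 2, seed = 13)
  clamp <- tiny_clamp(2, 40, seed = 30)
  whole <- run_network(net, "learn", clamp = clamp, seed = 5)
  first <- run_network(net, "learn",
                       clamp = spike_raster(clamp$spikes[, 1:20]), seed = 5)
  second <- run_network(net, "learn",
                        clamp = spike_raster(clamp$spikes[, 21:40]),
                        init_state = first$state)
  expect_equal(second$phi[, 1], whole$phi[, 21])
  expect_equal(second$eta[, 1], whole$eta[, 21])
})
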