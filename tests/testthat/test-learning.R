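test_that("post-synaptic factor matches its closed forms", {
  p0 <- neuron_params(eta0 = 0)
  # constant-rate neuron: rho dt = 1 at u = 0; build a custom case with
  # rho dt = 0.01 via delta_u scaling is awkward, so check directly on a trace
  net <- dual_network(2, 0, params = p0, seed = 1, init_sd = 0)
  clamp <- spike_raster(matrix(c(0L, 1L, 0L, 0L), 2, 2))
  tr <- run_network(net, "learn", clamp = clamp)
  PF <- post_factor(tr, "G")
  expect_equal(PF, (clamp$spikes - tr$rho_g * p0$dt) / p0$delta_u)
  # martingale property: expected factor vanishes when the sampling
  # probability equals rho dt
  z <- 0.42
  expect_equal(z * (1 - z) + (1 - z) * (0 - z), 0)
  # discrete form reduces to the continuous one for small rho dt and has
  # exactly zero mean under the Bernoulli sampler 1 - e^{-z}
  zs <- c(1e-6, 1e-3, 0.5, 1.5)
  cont_spike <- 1 - zs
  disc_spike <- zs / expm1(zs)
  expect_equal(disc_spike[1:2], cont_spike[1:2], tolerance = 1e-3)
  p_spike <- -expm1(-zs)
  expect_equal(p_spike * disc_spike + (1 - p_spike) * (-zs), rep(0, 4),
               tolerance = 1e-15)
})

test_that("fully observed gradient matches finite differences of the log-likelihood", {
  net <- dual_network(5, 0, seed = 2, init_sd = 0.3)
  data <- poisson_raster(rep(0.1, 5), 100, seed = 3)
  tr <- run_network(net, "learn", clamp = data)
  grad <- fully_observed_gradient(tr)
  fd <- fd_gradient(function(w) {
    np <- net; np$w_g <- w
    complete_log_likelihood(run_network(np, "learn", clamp = data), "G")
  }, net$w_g, spikevar:::topology_mask(net, "G"))
  expect_lt(max(abs(grad - fd)) / max(abs(fd)), 1e-5)

  # silent presynaptic neuron -> zero column
  data2 <- data
  data2$spikes[3, ] <- 0L
  tr2 <- run_network(net, "learn", clamp = data2)
  expect_equal(fully_observed_gradient(tr2)[, 3], rep(0, 5))
  expect_error(fully_observed_gradient(tr, window = integer(0)), "empty")
})

test_that("gradient ascent on the convex fully observed objective finds one optimum", {
  set.seed(13)
  data <- poisson_raster(c(0.05, 0.3, 0.15), 300, seed = 14)
  fit <- function(seed) {
    net <- dual_network(3, 0, seed = seed, init_sd = 0.2)
    for (it in 1:400) {
      tr <- run_network(net, "learn", clamp = data)
      net$w_g <- net$w_g + 2e-3 * fully_observed_gradient(tr)
    }
    net$w_g
  }
  w1 <- fit(1); w2 <- fit(2)
  expect_lt(max(abs(w1 - w2)), 0.02)
})

test_that("score-function expectation identities hold exactly by enumeration", {
  cfg <- learner_config()
  for (seed in 1:3) {
    net <- tiny_net(2, 2, seed = seed, init_sd = 0.2)
    clamp <- tiny_clamp(2, 4, seed = seed + 20)
    or <- enumeration_oracle(2, 4, clamp)
    eu <- oracle_expected_update(or, net, cfg, baseline = 1.3)
    # <grad log q>_q = 0
    expect_lt(max(abs(eu$expected_score)), 1e-10)
    # baseline removal leaves the expected update unchanged
    expect_lt(max(abs(eu$expected_dw_q_naive - eu$expected_dw_q_vr)), 1e-8)
    # both equal -mu_q * the finite-difference gradient of <F>_q
    fd <- fd_gradient(function(w) {
      np <- net; np$w_q <- w
      oracle_marginal(or, np)$expected_free_energy
    }, net$w_q, spikevar:::topology_mask(net, "Q"))
    expect_lt(max(abs(eu$expected_dw_q_naive / cfg$mu_q + fd)), 1e-8)
  }
})

test_that("batch updates preserve structural zeros and the F-hat = 0 contract", {
  net <- tiny_net(2, 2, seed = 7)
  tr <- run_network(net, "learn", clamp = tiny_clamp(2, 20), seed = 2)
  cfg <- learner_config()
  upd <- naive_batch_update(tr, f_hat = 0, cfg)
  expect_equal(upd$dw_q, matrix(0, 4, 4)) # zero modulator -> no Q update
  upd2 <- naive_batch_update(tr, free_energy_window(tr), cfg)
  expect_equal(diag(upd2$dw_g), rep(0, 4))
  expect_equal(diag(upd2$dw_q), rep(0, 4))
  expect_equal(upd2$dw_q[1:2, ], matrix(0, 2, 4)) # visible recognition rows
  # baseline = 0 reduces the variance-reduced rule to the naive one
  upd3 <- variance_reduced_update(tr, free_energy_window(tr), 0, cfg)
  expect_equal(upd3$dw_q, upd2$dw_q)
  expect_equal(upd3$dw_g, upd2$dw_g)
})

test_that("baseline removal reduces empirical update variance", {
  set.seed(31)
  net <- dual_network(6, 6, init_sd = 0.01 / sqrt(12), seed = 31)
  cfg <- learner_config()
  n_rep <- 120
  naive <- vr <- numeric(n_rep)
  baseline <- NA
  for (b in seq_len(n_rep)) {
    clamp <- poisson_raster(rep(0.05, 6), 100)
    tr <- run_network(net, "learn", clamp = clamp)
    f <- free_energy_window(tr)
    s <- spikevar:::score_matrix(tr, "Q")[7, 1]
    if (is.na(baseline)) baseline <- f
    naive[b] <- -cfg$mu_q * f * s
    vr[b] <- -cfg$mu_q * (f - baseline) * s
    baseline <- 0.9 * baseline + 0.1 * f
  }
  expect_lt(var(vr[21:n_rep]), var(naive[21:n_rep]))
})

test_that("Hebbian traces converge geometrically to a constant product", {
  net <- tiny_net(1, 1, seed = 3)
  traces <- hebbian_traces(net, tau_g = 10)
  tracker <- fe_tracker()
  cfg <- learner_config(learn_form = "continuous_limit")
  # constant synthetic bin: fixed product pf * phi
  bin <- list(x = c(1, 0), phi = c(0, 2), u_g = c(0, 0), rho_g = c(0.3, 0.3),
              u_q = c(0, 0), rho_q = c(0.3, 0.3), dt = 1)
  pf <- (bin$x - bin$rho_g * bin$dt) / net$params$delta_u
  target <- pf[1] * bin$phi[2] # post 1 <- pre 2
  a <- 1 / 10
  h <- 0
  for (k in 1:60) {
    st <- online_step(traces, bin, tracker, cfg)
    traces <- st$traces; tracker <- st$tracker
    h <- h + a * (target - h)
    expect_equal(traces$h_g[1, 2], h, tolerance = 1e-12)
  }
  expect_equal(traces$h_g[1, 2], target, tolerance = 2e-3)
  # diagonal stays structurally zero
  expect_equal(diag(traces$h_g), rep(0, 2))
})

test_that("zero novelty means no recognition update and a centered walk", {
  net <- tiny_net(2, 2, seed = 5)
  tr <- run_network(net, "learn", clamp = tiny_clamp(2, 10), seed = 4)
  traces <- hebbian_traces(net, 10)
  cfg <- learner_config()
  bin <- bin_slice(tr, 3)
  # a frozen tracker with matched averages keeps e_N at (numerically) zero
  tk <- fe_tracker(1e15, 1e15, fast_init = 1, slow_init = 1)
  st <- online_step(traces, bin, tk, cfg)
  expect_lt(max(abs(st$dw_q)), 1e-12)
  expect_gt(max(abs(st$dw_g)), 0)
})

test_that("time-averaged online generative updates match the batch gradient", {
  net <- tiny_net(3, 2, seed = 6)
  clamp <- poisson_raster(c(0.05, 0.2, 0.1), 10000, seed = 61)
  tr <- run_network(net, "learn", clamp = clamp, seed = 62)
  cfg <- learner_config(learn_form = "continuous_limit")
  traces <- hebbian_traces(net, cfg$tau_g)
  tracker <- fe_tracker()
  acc <- matrix(0, 5, 5)
  for (t in seq_len(10000)) {
    st <- online_step(traces, bin_slice(tr, t), tracker, cfg)
    traces <- st$traces; tracker <- st$tracker
    acc <- acc + st$dw_g
  }
  batch <- cfg$mu_g * fully_observed_gradient(tr) * net$params$dt
  expect_lt(max(abs(acc - batch)) / max(abs(batch)), 0.05)
})

test_that("the simplified rule reduces to the generative rule without hidden neurons", {
  net <- tiny_net(3, 0, seed = 8)
  tr <- run_network(net, "learn", clamp = tiny_clamp(3, 15), seed = 2)
  cfg <- learner_config()
  tr_o <- hebbian_traces(net, cfg$tau_g)
  tr_s <- hebbian_traces(net, cfg$tau_g)
  tk_o <- fe_tracker(); tk_s <- fe_tracker()
  for (t in 1:15) {
    so <- online_step(tr_o, bin_slice(tr, t), tk_o, cfg)
    ss <- simplified_step(tr_s, bin_slice(tr, t), tk_s, cfg)
    tr_o <- so$traces; tk_o <- so$tracker
    tr_s <- ss$traces; tk_s <- ss$tracker
    expect_equal(ss$dw, so$dw_g, tolerance = 1e-12)
    expect_equal(ss$f_t, so$f_t, tolerance = 1e-12) # all neurons visible
  }
})

test_that("tying recognition to generative weights makes hidden dynamics identical", {
  net <- tie_recognition_weights(tiny_net(2, 2, seed = 9, init_sd = 0.2))
  hid <- hidden_idx(net)
  expect_equal(net$w_q[hid, ], net$w_g[hid, ])
  tr <- run_network(net, "learn", clamp = tiny_clamp(2, 10), seed = 3)
  expect_equal(tr$rho_q[hid, ], tr$rho_g[hid, ])
})

test_that("variance scaling: baseline removal flattens the growth with N", {
  tab <- variance_scaling_experiment(c(4, 8), n_batches = 120, seed = 5,
                                     batch_bins = 100, warmup = 20)
  expect_true(all(tab$var_vr < tab$var_naive))
  expect_error(variance_scaling_experiment(4), "at least 2")
})
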