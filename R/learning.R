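# Learning rules: fully observed ML gradient, naive and variance-reduced
# score-function batch updates, online three-factor rule, merged-network
# simplification, and the variance-scaling study.

#' Learner configuration
#'
#' Learning rates and time constants of the plasticity rules. Defaults are
#' the simulation constants used by the benchmarks: both learning rates
#' `1e-5`, fast moving-average time constant 10 ms, baseline time constant
#' 100 ms, 200 ms batches. Updates are scaled by `dt` per bin so that the
#' learning-rate semantics are per-ms and invariant to re-binning.
#'
#' @param mu_g learning rate of the generative weights.
#' @param mu_q learning rate of the recognition weights.
#' @param tau_g time constant (ms) of the Hebbian traces and of the fast
#'   free-energy average.
#' @param tau_baseline time constant (ms) of the slow free-energy baseline.
#' @param variant learning-rule variant, one of `"naive_batch"`,
#'   `"vr_batch"`, `"online"`, `"simplified"`, `"fully_observed"`.
#' @param batch_ms batch window length T (ms).
#' @param baseline_decay per-batch retention of the exponential moving
#'   average used as batch baseline; the default 0.9 gives an effective
#'   window of about 10 batches.
#' @param baseline_warmup batches used to estimate the baseline (as a plain
#'   running mean) before the first recognition-weight update is applied.
#'   The error signal is only defined relative to a baseline averaged over
#'   several previous batches; applying score-function updates before one
#'   exists exposes the weights to raw batch-to-batch free-energy swings,
#'   which can be thousands of nats on structured data.
#' @param learn_form likelihood convention for all training-time gradients
#'   and modulators (post factors, batch free energy, online novelty
#'   input). The default `"discrete_exact"` differentiates the exact
#'   likelihood of the finite-bin Bernoulli process the simulator
#'   implements; the `"continuous_limit"` forms are its \eqn{\rho dt \to 0}
#'   limit. At the default physical constants an untrained network sits at
#'   \eqn{z = \rho\,dt \approx 0.6}, where the continuous-limit
#'   recognition score has per-bin mean \eqn{(1-e^{-z}) - z \approx -0.17}
#'   under the sampler (a large deterministic component in the summed
#'   batch score), and the continuous generative gradient of a saturated
#'   neuron never vanishes — both destabilize learning. The discrete
#'   forms have exactly zero-mean scores and stay bounded under
#'   saturation. Evaluation quantities keep their own form arguments.
#' @return An object of class `learner_config`.
#' @export
learner_config <- function(mu_g = 1e-5, mu_q = 1e-5, tau_g = 10,
                           tau_baseline = 100,
                           variant = c("vr_batch", "naive_batch", "online",
                                       "simplified", "fully_observed"),
                           batch_ms = 200, baseline_decay = 0.9,
                           baseline_warmup = 10,
                           learn_form = c("discrete_exact", "continuous_limit")) {
  variant <- match.arg(variant)
  learn_form <- match.arg(learn_form)
  if (mu_g <= 0 || mu_q <= 0) stop("learning rates must be positive")
  if (tau_g <= 0 || tau_baseline <= 0) stop("time constants must be positive")
  if (batch_ms <= 0) stop("`batch_ms` must be positive")
  if (baseline_decay < 0 || baseline_decay >= 1) stop("`baseline_decay` must be in [0, 1)")
  if (baseline_warmup < 1) stop("`baseline_warmup` must be at least 1")
  structure(list(mu_g = mu_g, mu_q = mu_q, tau_g = tau_g,
                 tau_baseline = tau_baseline, variant = variant,
                 batch_ms = batch_ms, baseline_decay = baseline_decay,
                 baseline_warmup = as.integer(baseline_warmup),
                 learn_form = learn_form),
            class = "learner_config")
}

#' Post-synaptic learning factor
#'
#' The neuron-local factor obtained by differentiating the log intensity:
#' for the exponential escape rate \eqn{g'/g = 1/\Delta u}, so under the
#' continuous-limit likelihood the factor is
#' \eqn{[X_i(t) - \rho_i(t)\,dt] / \Delta u} — spike minus expected spike,
#' scaled by the firing sensitivity. Under the `"discrete_exact"` form the
#' factor is the exact score of the finite-bin Bernoulli process,
#' \eqn{[X\, z/(e^{z}-1) - (1-X)\,z]/\Delta u} with \eqn{z = \rho\,dt},
#' which reduces to the continuous form as \eqn{z \to 0}. The discrete form
#' has exactly zero mean under the sampler and is what the enumeration
#' oracle differentiates.
#'
#' @param trace a learn-mode `network_trace`.
#' @param which `"G"` or `"Q"` — which intensity set to use.
#' @param neuron,t_bin optional scalar indices; when omitted the full
#'   (neuron x bin) factor matrix is returned.
#' @param form likelihood form, as in [complete_log_likelihood()].
#' @return Scalar or matrix of post-synaptic factors.
#' @export
post_factor <- function(trace, which = c("G", "Q"), neuron = NULL, t_bin = NULL,
                        form = c("continuous_limit", "discrete_exact")) {
  which <- match.arg(which)
  form <- match.arg(form)
  stopifnot(inherits(trace, "network_trace"))
  RHO <- if (which == "G") trace$rho_g else trace$rho_q
  if (is.null(RHO)) stop("trace does not contain intensities for the ", which, " network")
  p <- trace$params
  X <- trace$raster$spikes
  z <- RHO * p$dt
  PF <- if (form == "continuous_limit") {
    (X - z) / p$delta_u
  } else {
    (X * z / expm1(z) - (1 - X) * z) / p$delta_u
  }
  if (!is.null(neuron) && !is.null(t_bin)) PF[neuron, t_bin] else PF
}

# Per-neuron post factor and per-bin log-likelihood terms for one bin,
# in either likelihood convention (vector versions used by the online loop).
.pf_vec <- function(x, rho, dt, delta_u, form) {
  z <- rho * dt
  if (form == "continuous_limit") {
    (x - z) / delta_u
  } else {
    (x * z / expm1(z) - (1 - x) * z) / delta_u
  }
}

.ll_vec <- function(x, rho, u, dt, params, form) {
  z <- rho * dt
  if (form == "continuous_limit") {
    x * .log_rho(u, params) - z
  } else {
    x * log(-expm1(-z)) - (1 - x) * z
  }
}

# Accumulated score matrix S_ij = sum_t pf_i(t) phi_j(t), masked to the
# structural support of the requested synapse set.
score_matrix <- function(trace, which = c("G", "Q"),
                         form = c("continuous_limit", "discrete_exact"),
                         window = NULL) {
  which <- match.arg(which)
  form <- match.arg(form)
  PF <- post_factor(trace, which, form = form)
  if (is.null(window)) window <- seq_len(ncol(PF))
  if (length(window) == 0L) stop("empty window")
  S <- PF[, window, drop = FALSE] %*% t(trace$phi[, window, drop = FALSE])
  diag(S) <- 0
  if (which == "Q" && trace$n_visible > 0) S[seq_len(trace$n_visible), ] <- 0
  S
}

#' Maximum-likelihood gradient of a fully observed network
#'
#' Gradient of the continuous-limit complete-data log-likelihood with
#' respect to the generative weights at fixed spikes:
#' \eqn{\partial L / \partial w_{ij} = \sum_t \mathrm{pf}_i(t)\,\phi_j(t)},
#' the summed product of the post-synaptic factor and the presynaptic EPSP
#' trace. For a network without hidden neurons the objective is convex, so
#' gradient ascent finds the global maximum. The same expression, over all
#' rows, is the generative-side update of the partially observed model.
#'
#' @param trace a learn-mode `network_trace`.
#' @param window optional integer range of bins.
#' @return A post x pre gradient matrix (zero diagonal).
#' @export
fully_observed_gradient <- function(trace, window = NULL) {
  score_matrix(trace, "G", "continuous_limit", window)
}

#' Batch learning updates
#'
#' `naive_batch_update()` implements the unmodified stochastic gradients of
#' the free energy over one batch: the generative weights follow the
#' Hebbian maximum-likelihood gradient,
#' \eqn{\Delta w^G = \mu^G \sum_t \mathrm{pf}^G_i(t)\phi_j(t)}, while the
#' recognition weights follow the score-function (REINFORCE) estimator in
#' which the whole-batch free-energy point estimate \eqn{\hat F(T)} acts as
#' a global modulator:
#' \eqn{\Delta w^Q = -\mu^Q\,\hat F(T) \sum_t \mathrm{pf}^Q_i(t)\phi_j(t)}.
#'
#' `variance_reduced_update()` replaces \eqn{\hat F(T)} by the error signal
#' \eqn{e(T) = \hat F(T) - \bar F}, where the baseline \eqn{\bar F} is a
#' moving average over previous batches. Because the baseline does not
#' depend on the current batch's hidden spikes, the expected update is
#' unchanged while its variance drops from quadratic to roughly linear
#' growth in the network size.
#'
#' @param trace a learn-mode `network_trace` over the batch window.
#' @param f_hat the windowed free-energy point estimate \eqn{\hat F(T)} for
#'   the batch (see [free_energy_window()]); it must be computed with the
#'   same `form`.
#' @param cfg a [learner_config()]; `cfg$learn_form` selects the
#'   likelihood convention unless `form` overrides it.
#' @param baseline moving-average baseline \eqn{\bar F} from previous batches.
#' @param form likelihood convention for the post factors (see
#'   [post_factor()] and `learn_form` in [learner_config()]); `f_hat`
#'   must be computed in the same form.
#' @return A list with weight increments `dw_g` and `dw_q` (structural
#'   zeros preserved).
#' @export
naive_batch_update <- function(trace, f_hat, cfg, form = cfg$learn_form) {
  stopifnot(inherits(cfg, "learner_config"), is.numeric(f_hat), length(f_hat) == 1L)
  form <- match.arg(form, c("continuous_limit", "discrete_exact"))
  dw_g <- cfg$mu_g * score_matrix(trace, "G", form)
  dw_q <- if (trace$n_hidden > 0) {
    -cfg$mu_q * f_hat * score_matrix(trace, "Q", form)
  } else {
    matrix(0, nrow(dw_g), ncol(dw_g))
  }
  list(dw_g = dw_g, dw_q = dw_q)
}

#' @rdname naive_batch_update
#' @export
variance_reduced_update <- function(trace, f_hat, baseline, cfg,
                                    form = cfg$learn_form) {
  stopifnot(is.numeric(baseline), length(baseline) == 1L)
  naive_batch_update(trace, f_hat - baseline, cfg, form)
}

#' Hebbian eligibility traces
#'
#' Per-synapse low-pass filters of the product between the post-synaptic
#' factor and the presynaptic EPSP trace, one matrix per synapse set:
#' \eqn{H_{ij} \leftarrow H_{ij} + (dt/\tau_G)(\mathrm{pf}_i\,\phi_j -
#' H_{ij})}. Structurally absent synapses (diagonal; visible recognition
#' rows) stay at zero.
#'
#' @param net a [dual_network()]; fixes sizes and masks.
#' @param tau_g trace time constant (ms).
#' @return An object of class `hebbian_traces` with matrices `h_g`, `h_q`.
#' @export
hebbian_traces <- function(net, tau_g = 10) {
  stopifnot(inherits(net, "dual_network"), tau_g > 0)
  n <- net$n_visible + net$n_hidden
  structure(list(h_g = matrix(0, n, n), h_q = matrix(0, n, n),
                 mask_g = topology_mask(net, "G"),
                 mask_q = topology_mask(net, "Q"),
                 tau_g = tau_g, n_visible = net$n_visible,
                 n_hidden = net$n_hidden, params = net$params),
            class = "hebbian_traces")
}

# One-bin slice of a learn-mode trace, in the form online_step() consumes.
#' @rdname online_step
#' @param trace a learn-mode `network_trace`.
#' @param t_bin bin index.
#' @export
bin_slice <- function(trace, t_bin) {
  if (trace$mode == "generate") stop("online learning requires a clamped trace")
  list(x = trace$raster$spikes[, t_bin],
       phi = trace$phi[, t_bin],
       u_g = trace$u_g[, t_bin], rho_g = trace$rho_g[, t_bin],
       u_q = trace$u_q[, t_bin], rho_q = trace$rho_q[, t_bin],
       dt = trace$params$dt)
}

#' Online three-factor learning step
#'
#' The per-bin form of the variance-reduced rule: batch sums are replaced
#' by the moving-average Hebbian traces, the batch free-energy baseline by
#' the running novelty signal \eqn{e_N(t)}, and updates are applied at
#' every time step.
#'
#' Each call (once per bin, in learn mode) advances the Hebbian traces of
#' both synapse sets, feeds the bin's instantaneous free energy into the
#' novelty tracker, and returns the weight increments
#' \deqn{\Delta w^G_{ij} = \mu^G H^G_{ij}\,dt, \qquad
#'       \Delta w^Q_{ij} = -\mu^Q\,e_N(t)\,H^Q_{ij}\,dt.}
#' The generative update is a two-factor Hebbian rule; the recognition
#' update is a three-factor rule in which the novelty signal is the global
#' modulator: positive covariance between the Hebbian trace and the free
#' energy depresses the synapse, negative covariance potentiates it, and a
#' null covariance leaves the weight on a centered random walk.
#'
#' @param traces a [hebbian_traces()] object.
#' @param bin a one-bin slice as produced by [bin_slice()] (fields `x`,
#'   `phi`, `u_g`, `rho_g`, `u_q`, `rho_q`, `dt`).
#' @param tracker an [fe_tracker()].
#' @param cfg a [learner_config()].
#' @return List with updated `traces` and `tracker`, the increments `dw_g`
#'   and `dw_q`, the novelty signal `e_n` and the bin free energy `f_t`.
#' @export
online_step <- function(traces, bin, tracker, cfg) {
  stopifnot(inherits(traces, "hebbian_traces"), inherits(tracker, "fe_tracker"),
            inherits(cfg, "learner_config"))
  p <- traces$params
  dt <- bin$dt
  nv <- traces$n_visible
  hid <- if (traces$n_hidden > 0) nv + seq_len(traces$n_hidden) else integer(0)

  pf_g <- .pf_vec(bin$x, bin$rho_g, dt, p$delta_u, cfg$learn_form)
  pf_q <- .pf_vec(bin$x, bin$rho_q, dt, p$delta_u, cfg$learn_form)
  a <- dt / traces$tau_g
  traces$h_g <- traces$h_g + a * (outer(pf_g, bin$phi) - traces$h_g)
  traces$h_g[!traces$mask_g] <- 0
  traces$h_q <- traces$h_q + a * (outer(pf_q, bin$phi) - traces$h_q)
  traces$h_q[!traces$mask_q] <- 0

  f_t <- -sum(.ll_vec(bin$x, bin$rho_g, bin$u_g, dt, p, cfg$learn_form))
  if (length(hid) > 0) {
    f_t <- f_t + sum(.ll_vec(bin$x[hid], bin$rho_q[hid], bin$u_q[hid], dt, p,
                             cfg$learn_form))
  }
  st <- update_novelty(tracker, f_t, dt)

  list(traces = traces, tracker = st$tracker,
       dw_g = cfg$mu_g * traces$h_g * dt,
       dw_q = -cfg$mu_q * st$e_n * traces$h_q * dt,
       e_n = st$e_n, f_t = f_t)
}

#' Online step of the merged-network (simplified) model
#'
#' In the simplified model the recognition weights onto hidden neurons are
#' constrained to equal the generative weights, so the forward dynamics of
#' the generative model serves as the posterior proposal. The free energy
#' then reduces to the visible-neuron terms only, and the tied weight set
#' receives a single update: synapses onto visible neurons follow the
#' two-factor Hebbian rule, synapses onto hidden neurons follow the
#' three-factor rule gated by the (visible-only) novelty signal.
#'
#' `bin` must come from a network whose hidden recognition rows equal the
#' generative ones (see [tie_recognition_weights()]), in which case
#' `rho_q` and `rho_g` coincide on hidden neurons.
#'
#' @inheritParams online_step
#' @return List with updated `traces` and `tracker`, a single increment
#'   `dw` for the tied weight matrix, `e_n` and `f_t`.
#' @export
simplified_step <- function(traces, bin, tracker, cfg) {
  stopifnot(inherits(traces, "hebbian_traces"), inherits(tracker, "fe_tracker"))
  p <- traces$params
  dt <- bin$dt
  nv <- traces$n_visible
  vis <- seq_len(nv)
  hid <- if (traces$n_hidden > 0) nv + seq_len(traces$n_hidden) else integer(0)

  pf <- .pf_vec(bin$x, bin$rho_g, dt, p$delta_u, cfg$learn_form)
  a <- dt / traces$tau_g
  traces$h_g <- traces$h_g + a * (outer(pf, bin$phi) - traces$h_g)
  traces$h_g[!traces$mask_g] <- 0

  f_t <- -sum(.ll_vec(bin$x[vis], bin$rho_g[vis], bin$u_g[vis], dt, p,
                      cfg$learn_form))
  st <- update_novelty(tracker, f_t, dt)

  dw <- matrix(0, nrow(traces$h_g), ncol(traces$h_g))
  dw[vis, ] <- cfg$mu_g * traces$h_g[vis, ] * dt
  if (length(hid) > 0) {
    dw[hid, ] <- -cfg$mu_q * st$e_n * traces$h_g[hid, ] * dt
  }
  list(traces = traces, tracker = st$tracker, dw = dw,
       e_n = st$e_n, f_t = f_t)
}

#' Tie the recognition weights to the generative ones
#'
#' Copies the generative hidden-row weights into the recognition matrix,
#' producing the merged-network model in which the generative forward
#' dynamics doubles as the posterior proposal.
#'
#' @param net a [dual_network()].
#' @return The network with `w_q` hidden rows equal to `w_g` hidden rows.
#' @export
tie_recognition_weights <- function(net) {
  if (net$n_hidden > 0) {
    hid <- hidden_idx(net)
    net$w_q[hid, ] <- net$w_g[hid, ]
    diag(net$w_q) <- 0
  }
  net
}

#' Empirical variance scaling of the recognition gradient
#'
#' Measures, at fixed random weights (no learning), the across-batch
#' variance of a recognition-synapse batch update with and without baseline
#' removal, as a function of the number of hidden neurons. The naive
#' score-function gradient is modulated by the whole-network free energy,
#' whose mean grows linearly with network size, so its variance grows
#' roughly quadratically; subtracting a running baseline centers the
#' modulator and reduces the growth to roughly linear.
#'
#' Networks have `n_visible = N` visible neurons driven by independent
#' Poisson spikes and `N` hidden neurons, so the total size scales with
#' the swept parameter. The fixed weights are drawn with standard
#' deviation `coupling_scale / sqrt(2 N)`, which keeps each neuron's
#' synaptic input variance constant across the sweep and therefore keeps
#' the network in the weak-coupling regime that the quadratic-vs-linear
#' scaling argument assumes; at a size-independent weight scale, recurrent
#' correlations grow with N and contaminate both slopes. The baseline is
#' the same exponential moving average over previous batches used during
#' training; the first `warmup` batches are excluded from the variance
#' estimates.
#'
#' @param n_hidden_list numbers of hidden neurons to sweep (at least 2).
#' @param n_batches independent batches per condition.
#' @param cfg a [learner_config()].
#' @param seed integer seed.
#' @param batch_bins bins per batch.
#' @param drive_rate rate (kHz) of the Poisson drive on visible neurons.
#' @param coupling_scale numerator of the size-normalized weight scale.
#' @param warmup batches discarded while the baseline settles.
#' @return A `data.frame` with columns `n_hidden`, `var_naive`, `var_vr`
#'   and attributes `slope_naive`, `slope_vr` (fitted log-log slopes of
#'   variance versus N).
#' @export
variance_scaling_experiment <- function(n_hidden_list, n_batches = 500,
                                        cfg = learner_config(), seed = 1,
                                        batch_bins = 200, drive_rate = 0.05,
                                        coupling_scale = 0.01, warmup = 50) {
  if (length(n_hidden_list) < 2L) stop("need at least 2 values of N")
  set.seed(seed)
  rows <- lapply(n_hidden_list, function(N) {
    net <- dual_network(N, N, init_sd = coupling_scale / sqrt(2 * N),
                        seed = sample.int(2^31 - 1, 1))
    # track one fixed recognition synapse: first hidden neuron <- first visible
    i <- N + 1L; j <- 1L
    baseline <- NA_real_
    upd_naive <- upd_vr <- numeric(n_batches)
    for (b in seq_len(n_batches)) {
      clamp <- poisson_raster(rep(drive_rate, N), batch_bins, dt = net$params$dt)
      tr <- run_network(net, "learn", clamp = clamp)
      f <- free_energy_window(tr, form = cfg$learn_form)
      s <- score_matrix(tr, "Q", cfg$learn_form)[i, j]
      if (is.na(baseline)) baseline <- f
      upd_naive[b] <- -cfg$mu_q * f * s
      upd_vr[b] <- -cfg$mu_q * (f - baseline) * s
      baseline <- cfg$baseline_decay * baseline + (1 - cfg$baseline_decay) * f
    }
    keep <- seq.int(warmup + 1L, n_batches)
    data.frame(n_hidden = N,
               var_naive = stats::var(upd_naive[keep]),
               var_vr = stats::var(upd_vr[keep]))
  })
  out <- do.call(rbind, rows)
  fit <- function(v) unname(stats::coef(stats::lm(log(v) ~ log(out$n_hidden)))[2])
  attr(out, "slope_naive") <- fit(out$var_naive)
  attr(out, "slope_vr") <- fit(out$var_vr)
  out
}
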