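# Model evaluation: importance-sampling likelihood estimation, posterior
# inference and generative sampling wrappers, and the exhaustive-enumeration
# oracle used as exact ground truth on tiny instances.

#' Generative sampling and posterior inference
#'
#' Thin wrappers over [run_network()]: `sample_generative()` runs the
#' network with the recognition synapses switched off (a sample from the
#' learned generative model, e.g. for inspecting spontaneous activity);
#' `infer_hidden()` clamps the visible neurons to data and runs the
#' recognition synapses, returning an approximate posterior sample of the
#' hidden spike trains.
#'
#' @param net a [dual_network()].
#' @param duration_bins bins to simulate.
#' @param data a [spike_raster()] over the visible neurons.
#' @param seed optional integer seed.
#' @return A `network_trace`.
#' @export
sample_generative <- function(net, duration_bins, seed = NULL) {
  run_network(net, "generate", duration_bins = duration_bins, seed = seed)
}

#' @rdname sample_generative
#' @export
infer_hidden <- function(net, data, seed = NULL) {
  run_network(net, "infer", clamp = data, seed = seed)
}

# Simulate n_samples independent recognition-network chains clamped to the
# same visible data, vectorized across chains; returns the per-chain
# free-energy point estimates F_hat(T).
.ensemble_free_energies <- function(net, clamp, n_samples, form) {
  p <- net$params
  nv <- net$n_visible; nh <- net$n_hidden; n <- nv + nh
  B <- n_bins(clamp)
  S <- n_samples
  decay_m <- exp(-p$dt / p$tau)
  decay_a <- exp(-p$dt / p$tau_adapt)
  PHI <- matrix(0, n, S)
  ETA <- matrix(0, n, S)
  Fhat <- numeric(S)
  hid <- nv + seq_len(nh)
  clip <- function(z) pmin(pmax(z, -500), 500)
  for (t in seq_len(B)) {
    UG <- net$w_g %*% PHI + ETA
    UQ <- net$w_q[hid, , drop = FALSE] %*% PHI + ETA[hid, , drop = FALSE]
    ZG <- clip((UG - p$theta) / p$delta_u)
    ZQ <- clip((UQ - p$theta) / p$delta_u)
    RG <- p$rho0 * exp(ZG)
    RQ <- p$rho0 * exp(ZQ)
    Xh <- matrix(stats::runif(nh * S) < -expm1(-p$dt * RQ), nh, S)
    X <- matrix(0, n, S)
    X[seq_len(nv), ] <- clamp$spikes[, t]
    X[hid, ] <- Xh
    lrg <- log(p$rho0) + ZG
    lrq <- log(p$rho0) + ZQ
    if (form == "continuous_limit") {
      llg <- X * lrg - RG * p$dt
      llq <- Xh * lrq - RQ * p$dt
    } else {
      llg <- X * log(-expm1(-RG * p$dt)) - (1 - X) * RG * p$dt
      llq <- Xh * log(-expm1(-RQ * p$dt)) - (1 - Xh) * RQ * p$dt
    }
    Fhat <- Fhat - colSums(llg) + colSums(llq)
    PHI <- PHI * decay_m + X
    ETA <- ETA * decay_a - p$eta0 * X
  }
  Fhat
}

#' Importance-sampling estimate of the data log-likelihood
#'
#' Estimates \eqn{\log p(X_V)} by drawing hidden spike trains from the
#' recognition network clamped to the data and averaging the exponentiated
#' negative free-energy point estimates:
#' \deqn{\log p(X_V) \approx \log \frac{1}{n}\sum_{s=1}^{n}
#'   e^{-\hat F(X_V, X_H^{(s)})},}
#' evaluated through a numerically stable log-sum-exp. With no hidden
#' neurons the free energy is deterministic and the estimate equals the
#' complete-data log-likelihood exactly. The estimator is consistent and,
#' at finite sample counts, biased low (Jensen).
#'
#' Data longer than `sample_ms` is tiled into non-overlapping evaluation
#' windows of that length (a trailing remainder is dropped); per-window
#' estimates and their Monte-Carlo standard errors are combined by
#' summation. The default protocol is 500 samples of 100 ms per window.
#'
#' @param net a [dual_network()].
#' @param data a [spike_raster()] over the visible neurons.
#' @param n_samples hidden samples per evaluation window.
#' @param sample_ms evaluation window length (ms).
#' @param form likelihood form used for \eqn{\hat F}. The default
#'   `"discrete_exact"` targets the exactly normalized finite-bin process
#'   (what the enumeration oracle computes), and is valid at any
#'   \eqn{\rho\,dt}; the `"continuous_limit"` form matches the learning
#'   objective's classical derivation but is only a probability in the
#'   \eqn{\rho\,dt \ll 1} regime — when the recognition proposal visits
#'   high intensities it produces meaningless importance weights.
#' @param seed optional integer seed.
#' @return An object of class `is_estimate`: list with `log_likelihood`
#'   (nats), `se` (delta-method Monte-Carlo standard error),
#'   `n_samples`, `sample_duration_ms`, `n_windows`, `per_window`
#'   (data.frame) and `per_sample_neg_free_energies` (windows x samples).
#' @export
estimate_log_likelihood <- function(net, data, n_samples = 500,
                                    sample_ms = 100,
                                    form = c("discrete_exact", "continuous_limit"),
                                    seed = NULL) {
  form <- match.arg(form)
  validate_network(net)
  stopifnot(inherits(data, "spike_raster"), n_samples >= 1)
  if (n_neurons(data) != net$n_visible) {
    stop("`data` must cover exactly the visible neurons")
  }
  p <- net$params
  win_bins <- as.integer(round(sample_ms / p$dt))
  if (win_bins < 1L) stop("`sample_ms` must cover at least one bin")
  n_windows <- n_bins(data) %/% win_bins
  if (n_windows < 1L) stop("data duration is shorter than the evaluation window")
  if (!is.null(seed)) set.seed(seed)

  NF <- matrix(NA_real_, n_windows, n_samples)
  ll_w <- se_w <- numeric(n_windows)
  for (w in seq_len(n_windows)) {
    cols <- ((w - 1L) * win_bins + 1L):(w * win_bins)
    clamp <- spike_raster(data$spikes[, cols, drop = FALSE], dt = p$dt)
    if (net$n_hidden == 0L) {
      tr <- run_network(net, "learn", clamp = clamp)
      ll <- complete_log_likelihood(tr, "G", neurons = NULL, form = form)
      NF[w, ] <- ll
      ll_w[w] <- ll
      se_w[w] <- 0
    } else {
      fh <- .ensemble_free_energies(net, clamp, n_samples, form)
      NF[w, ] <- -fh
      m <- max(-fh)
      if (!is.finite(m)) {
        warning("all importance weights vanished; estimate is -Inf")
        ll_w[w] <- -Inf
        se_w[w] <- Inf
      } else {
        wi <- exp(-fh - m)
        ll_w[w] <- m + log(mean(wi))
        se_w[w] <- stats::sd(wi) / (mean(wi) * sqrt(n_samples))
      }
    }
  }
  structure(
    list(log_likelihood = sum(ll_w), se = sqrt(sum(se_w^2)),
         n_samples = n_samples, sample_duration_ms = win_bins * p$dt,
         n_windows = n_windows,
         per_window = data.frame(window = seq_len(n_windows),
                                 log_likelihood = ll_w, se = se_w),
         per_sample_neg_free_energies = NF),
    class = "is_estimate"
  )
}

#' @export
print.is_estimate <- function(x, ...) {
  cat(sprintf(
    "importance-sampling estimate: log L = %.4f nats (SE %.4f), %d window(s) x %d samples of %g ms\n",
    x$log_likelihood, x$se, x$n_windows, x$n_samples, x$sample_duration_ms))
  invisible(x)
}

#' Exhaustive-enumeration oracle
#'
#' Exact ground truth on tiny instances: enumerates all
#' \eqn{2^{n_{hidden} \cdot n_{bins}}} hidden rasters compatible with a
#' clamped visible raster and computes, with the *exactly normalized*
#' discrete likelihood, the marginal \eqn{\log p(X_V)}, the exact
#' posterior over hidden rasters, the recognition probabilities
#' \eqn{q(X_H|X_V)}, the exact expected free energy
#' \eqn{\langle\hat F\rangle_q} and the gap
#' \eqn{KL(q\,\|\,p(X_H|X_V))}. These satisfy
#' \eqn{\langle\hat F\rangle_q + \log p(X_V) = KL \ge 0} to machine
#' precision, which is the identity the stochastic learners approximate.
#'
#' @param n_hidden,n_bins hidden population size and window length; the
#'   state space \eqn{2^{n_{hidden} n_{bins}}} is guarded at \eqn{2^{20}}.
#' @param clamp visible [spike_raster()] with `n_bins` columns.
#' @return `enumeration_oracle()` returns a guard object of class
#'   `enumeration_oracle`.
#' @export
enumeration_oracle <- function(n_hidden, n_bins, clamp) {
  stopifnot(inherits(clamp, "spike_raster"), n_hidden >= 0)
  if (ncol(clamp$spikes) != n_bins) stop("clamp must have `n_bins` columns")
  k <- n_hidden * n_bins
  if (k > 20) stop("state space 2^", k, " exceeds the 2^20 enumeration guard")
  structure(list(n_hidden = as.integer(n_hidden), n_bins = as.integer(n_bins),
                 clamp = clamp),
            class = "enumeration_oracle")
}

# All hidden rasters as a list of n_hidden x n_bins 0/1 matrices.
.enumerate_hidden <- function(oracle) {
  k <- oracle$n_hidden * oracle$n_bins
  lapply(seq_len(2^k) - 1L, function(code) {
    bits <- as.integer(intToBits(code)[seq_len(max(k, 1L))])
    if (k == 0L) bits <- integer(0)
    matrix(bits, nrow = oracle$n_hidden, ncol = oracle$n_bins)
  })
}

# log p^G(X) and log q(X_H | X_V) for one full raster, discrete form.
.oracle_terms <- function(net, oracle, hidden_spikes) {
  full <- rbind(oracle$clamp$spikes, hidden_spikes)
  tr <- trace_given_raster(net, spike_raster(full, dt = net$params$dt))
  logp <- complete_log_likelihood(tr, "G", form = "discrete_exact")
  logq <- if (net$n_hidden > 0) {
    complete_log_likelihood(tr, "Q", form = "discrete_exact")
  } else 0
  fhat <- free_energy_window(tr, "full", "discrete_exact")
  list(logp = logp, logq = logq, fhat = fhat, trace = tr)
}

#' @rdname enumeration_oracle
#' @param oracle an `enumeration_oracle`.
#' @param net a [dual_network()] whose sizes match the oracle.
#' @return `oracle_marginal()` returns a list with `log_p_visible`,
#'   `posterior` and `q_prob` (probability vectors over the enumerated
#'   hidden rasters), `expected_free_energy`, `kl` and the enumeration
#'   order in `hidden_rasters`.
#' @export
oracle_marginal <- function(oracle, net) {
  stopifnot(inherits(oracle, "enumeration_oracle"))
  validate_network(net)
  if (net$n_hidden != oracle$n_hidden) stop("hidden counts differ")
  if (net$n_visible != n_neurons(oracle$clamp)) stop("visible counts differ")
  hs <- .enumerate_hidden(oracle)
  terms <- lapply(hs, function(h) .oracle_terms(net, oracle, h))
  logp <- vapply(terms, `[[`, numeric(1), "logp")
  logq <- vapply(terms, `[[`, numeric(1), "logq")
  fhat <- vapply(terms, `[[`, numeric(1), "fhat")
  m <- max(logp)
  log_pv <- m + log(sum(exp(logp - m)))
  posterior <- exp(logp - log_pv)
  q_prob <- exp(logq)
  efe <- sum(q_prob * fhat)
  kl <- sum(ifelse(q_prob > 0, q_prob * (logq - (logp - log_pv)), 0))
  list(log_p_visible = log_pv, posterior = posterior, q_prob = q_prob,
       expected_free_energy = efe, kl = kl, hidden_rasters = hs)
}

#' Exact expected learning updates by enumeration
#'
#' Averages the batch updates over *all* hidden rasters weighted by their
#' exact recognition probabilities, giving the exact expectations that the
#' stochastic score-function estimators approximate: the expected
#' recognition score matrix (which is exactly zero), and the expected
#' naive and baseline-removed recognition updates (which coincide, since
#' the baseline is independent of the hidden spikes).
#'
#' @inheritParams oracle_marginal
#' @param cfg a [learner_config()].
#' @param baseline baseline value for the variance-reduced expectation.
#' @param form likelihood form (the identities are exact for
#'   `"discrete_exact"`, the form under which the sampler is the true
#'   process).
#' @return List with matrices `expected_score` (recognition score),
#'   `expected_dw_q_naive`, `expected_dw_q_vr` and `expected_dw_g`.
#' @export
oracle_expected_update <- function(oracle, net, cfg = learner_config(),
                                   baseline = 0,
                                   form = c("discrete_exact", "continuous_limit")) {
  form <- match.arg(form)
  stopifnot(inherits(oracle, "enumeration_oracle"))
  hs <- .enumerate_hidden(oracle)
  n <- net$n_visible + net$n_hidden
  es <- dwn <- dwv <- dwg <- matrix(0, n, n)
  for (h in hs) {
    ot <- .oracle_terms(net, oracle, h)
    qp <- exp(ot$logq)
    s_q <- score_matrix(ot$trace, "Q", form)
    f <- free_energy_window(ot$trace, "full", form)
    upd_n <- naive_batch_update(ot$trace, f, cfg, form)
    upd_v <- variance_reduced_update(ot$trace, f, baseline, cfg, form)
    es <- es + qp * s_q
    dwn <- dwn + qp * upd_n$dw_q
    dwv <- dwv + qp * upd_v$dw_q
    dwg <- dwg + qp * upd_n$dw_g
  }
  list(expected_score = es, expected_dw_q_naive = dwn,
       expected_dw_q_vr = dwv, expected_dw_g = dwg)
}
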