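# Point-process log-likelihoods, free energy, novelty signal.

# Per-bin log-likelihood terms for a spike matrix X and intensity matrix RHO.
# "continuous_limit": X log(rho) - rho dt  (density of the point process,
#   the dt -> 0 limit; log rho computed stably from u when available).
# "discrete_exact":   X log(1 - e^{-rho dt}) - (1 - X) rho dt  (exact log
#   probability mass of the Bernoulli sampler; normalizes over rasters).
.per_bin_ll <- function(X, RHO, dt, form, LOGRHO = NULL) {
  z <- RHO * dt
  if (form == "continuous_limit") {
    lr <- if (is.null(LOGRHO)) log(RHO) else LOGRHO
    X * lr - z
  } else {
    X * log(-expm1(-z)) - (1 - X) * z
  }
}

# Stable log intensities from membrane potentials:
# log rho = log rho0 + (u - theta)/delta_u (never exponentiate-then-log).
.log_rho <- function(U, params) {
  log(params$rho0) + (U - params$theta) / params$delta_u
}

#' Complete-data log-likelihood of a spike raster under one synapse set
#'
#' Sums the per-neuron per-bin point-process terms of a simulated (or
#' deterministically evaluated) trace. Under the generative weights (`which
#' = "G"`) the default neuron set is the whole population; under the
#' recognition weights (`which = "Q"`) it is the hidden neurons only, since
#' the recognition network defines a distribution over hidden spikes given
#' the visible ones — requesting Q-terms for visible neurons is an error.
#'
#' Two likelihood forms are available. `"continuous_limit"` is the
#' point-process density used by the learning rules, with per-bin term
#' \eqn{X \log\rho - \rho\,dt} (intensities in kHz, time in ms, so values
#' are in nats). `"discrete_exact"` is the exact log probability mass of
#' the finite-bin Bernoulli sampler, \eqn{X\log(1 - e^{-\rho dt}) -
#' (1-X)\rho dt}; it sums to one over all rasters and backs the
#' enumeration oracle. The two agree to first order in \eqn{\rho\,dt}.
#'
#' @param trace a `network_trace` containing the intensities for the
#'   requested synapse set (`"learn"` mode traces contain both).
#' @param which `"G"` or `"Q"`.
#' @param neurons optional integer subset of neuron indices.
#' @param form `"continuous_limit"` (default) or `"discrete_exact"`.
#' @param window optional integer range of bins (default: all).
#' @return Scalar log-likelihood in nats.
#' @export
complete_log_likelihood <- function(trace, which = c("G", "Q"), neurons = NULL,
                                    form = c("continuous_limit", "discrete_exact"),
                                    window = NULL) {
  which <- match.arg(which)
  form <- match.arg(form)
  stopifnot(inherits(trace, "network_trace"))
  n <- trace$n_visible + trace$n_hidden
  hid <- if (trace$n_hidden > 0) trace$n_visible + seq_len(trace$n_hidden) else integer(0)
  if (is.null(neurons)) {
    neurons <- if (which == "G") seq_len(n) else hid
  }
  if (length(neurons) == 0L) return(0)
  if (which == "Q" && any(neurons <= trace$n_visible)) {
    stop("the recognition network defines no likelihood for visible neurons")
  }
  RHO <- if (which == "G") trace$rho_g else trace$rho_q
  U <- if (which == "G") trace$u_g else trace$u_q
  if (is.null(RHO)) stop("trace does not contain intensities for the ", which, " network")
  if (is.null(window)) window <- seq_len(n_bins(trace$raster))
  X <- trace$raster$spikes[neurons, window, drop = FALSE]
  LL <- .per_bin_ll(X, RHO[neurons, window, drop = FALSE], trace$params$dt, form,
                    LOGRHO = .log_rho(U[neurons, window, drop = FALSE], trace$params))
  sum(LL)
}

#' Instantaneous and windowed free energy
#'
#' The instantaneous free energy of a learn-mode trace at bin \eqn{t} is
#' \deqn{\hat F_t = -\sum_{i \in V \cup H}\left[X_i \log\rho^G_i -
#'   \rho^G_i dt\right] + \sum_{i \in H}\left[X_i \log\rho^Q_i -
#'   \rho^Q_i dt\right],}
#' the per-bin difference between the recognition log-probability of the
#' hidden spikes and the generative log-likelihood of all spikes. Its sum
#' over a window is the point estimate \eqn{\hat F(T)} whose expectation
#' under the recognition distribution upper-bounds the negative data
#' log-likelihood. The `"simplified"` variant, used by the merged-network
#' model where recognition weights are tied to the generative ones, keeps
#' only the visible-neuron terms (hidden G- and Q-terms cancel exactly
#' under tying).
#'
#' Contributions are per bin, with the integral term discretized as
#' \eqn{\rho\,dt} (nats per bin).
#'
#' @param trace a `"learn"`-mode `network_trace` (a trace holding both
#'   intensity sets; generate-mode traces are rejected).
#' @param variant `"full"` or `"simplified"`.
#' @param form likelihood form, as in [complete_log_likelihood()].
#' @return `instantaneous_free_energy()`: numeric vector, one value per bin.
#'   `free_energy_window()`: scalar \eqn{\hat F(T)}, the sum over the window.
#' @export
instantaneous_free_energy <- function(trace, variant = c("full", "simplified"),
                                      form = c("continuous_limit", "discrete_exact")) {
  variant <- match.arg(variant)
  form <- match.arg(form)
  stopifnot(inherits(trace, "network_trace"))
  if (trace$mode == "generate") {
    stop("free energy requires a clamped (learn-mode) trace, not a generative sample")
  }
  if (is.null(trace$rho_g)) {
    stop("trace lacks generative intensities; run the network in 'learn' mode")
  }
  p <- trace$params
  X <- trace$raster$spikes
  vis <- seq_len(trace$n_visible)
  if (variant == "simplified") {
    LLv <- .per_bin_ll(X[vis, , drop = FALSE], trace$rho_g[vis, , drop = FALSE],
                       p$dt, form, .log_rho(trace$u_g[vis, , drop = FALSE], p))
    return(-colSums(LLv))
  }
  LLg <- .per_bin_ll(X, trace$rho_g, p$dt, form, .log_rho(trace$u_g, p))
  f <- -colSums(LLg)
  if (trace$n_hidden > 0) {
    hid <- trace$n_visible + seq_len(trace$n_hidden)
    LLq <- .per_bin_ll(X[hid, , drop = FALSE], trace$rho_q[hid, , drop = FALSE],
                       p$dt, form, .log_rho(trace$u_q[hid, , drop = FALSE], p))
    f <- f + colSums(LLq)
  }
  f
}

#' @rdname instantaneous_free_energy
#' @export
free_energy_window <- function(trace, variant = c("full", "simplified"),
                               form = c("continuous_limit", "discrete_exact")) {
  sum(instantaneous_free_energy(trace, variant, form))
}

#' Running novelty signal
#'
#' Two cascaded exponential moving averages of the instantaneous free
#' energy. The fast average (time constant `tau_g`) tracks the current
#' free energy; the slow baseline (time constant `tau_baseline`) filters
#' the *fast* average, so its effective time scale depends on both
#' constants. The novelty signal is their difference,
#' \eqn{e_N(t) = \bar F_{fast}(t) - \bar F_{slow}(t)}: an instantaneous
#' surprise measure relative to the slowly adapting background surprise
#' level. It is the global third factor that gates recognition-synapse
#' plasticity in the online rule.
#'
#' @param tau_g fast time constant (ms); default 10.
#' @param tau_baseline slow time constant (ms); default 100.
#' @param fast_init,slow_init cold-start values of the two averages. `NA`
#'   warm-starts both at the first observed free energy, which avoids a
#'   large spurious novelty transient at the beginning of a run.
#' @return `fe_tracker()` returns an object of class `fe_tracker`;
#'   `update_novelty()` returns a list with the updated `tracker` and the
#'   novelty signal `e_n`.
#' @export
#' @examples
#' tr <- fe_tracker()
#' st <- update_novelty(tr, f_instant = 2, dt = 1)
#' st$e_n
fe_tracker <- function(tau_g = 10, tau_baseline = 100,
                       fast_init = NA, slow_init = NA) {
  if (tau_g <= 0 || tau_baseline <= 0) stop("time constants must be positive")
  structure(list(fast_avg = fast_init, slow_baseline = slow_init,
                 tau_g = tau_g, tau_baseline = tau_baseline),
            class = "fe_tracker")
}

#' @rdname fe_tracker
#' @param tracker an `fe_tracker`.
#' @param f_instant instantaneous free energy value for the bin.
#' @param dt bin width (ms).
#' @export
update_novelty <- function(tracker, f_instant, dt) {
  stopifnot(inherits(tracker, "fe_tracker"))
  if (is.na(tracker$fast_avg)) {
    tracker$fast_avg <- f_instant
    tracker$slow_baseline <- f_instant
    return(list(tracker = tracker, e_n = 0))
  }
  tracker$fast_avg <- tracker$fast_avg +
    (dt / tracker$tau_g) * (f_instant - tracker$fast_avg)
  tracker$slow_baseline <- tracker$slow_baseline +
    (dt / tracker$tau_baseline) * (tracker$fast_avg - tracker$slow_baseline)
  list(tracker = tracker, e_n = tracker$fast_avg - tracker$slow_baseline)
}

#' Novelty trace over a whole free-energy series
#'
#' Convenience driver of [update_novelty()] over a vector of instantaneous
#' free energies; the result has the layout used by the experiment drivers'
#' TSV exports.
#'
#' @param f_vec numeric vector of per-bin instantaneous free energies.
#' @param tracker an [fe_tracker()]; its state is advanced through the series.
#' @param dt bin width (ms).
#' @return A `data.frame` with columns `bin`, `time_ms`, `f_instant`,
#'   `fast_avg`, `slow_baseline`, `e_n`, plus the final tracker in
#'   `attr(, "tracker")`.
#' @export
novelty_trace <- function(f_vec, tracker = fe_tracker(), dt = 1) {
  B <- length(f_vec)
  fast <- slow <- en <- numeric(B)
  for (t in seq_len(B)) {
    st <- update_novelty(tracker, f_vec[t], dt)
    tracker <- st$tracker
    fast[t] <- tracker$fast_avg
    slow[t] <- tracker$slow_baseline
    en[t] <- st$e_n
  }
  out <- data.frame(bin = seq_len(B) - 1L, time_ms = (seq_len(B) - 1L) * dt,
                    f_instant = f_vec, fast_avg = fast,
                    slow_baseline = slow, e_n = en)
  attr(out, "tracker") <- tracker
  out
}

#' @rdname novelty_trace
#' @param trace_df a data frame as returned by `novelty_trace()`.
#' @param path output TSV path.
#' @export
write_fe_tsv <- function(trace_df, path) {
  utils::write.table(trace_df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
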