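#' Elementary trace and intensity operations
#'
#' The building blocks of the discrete-time dynamics. EPSP traces follow
#' \eqn{\dot\phi = (X - \phi)/\tau} and are propagated *exactly* over one
#' bin: decay by \eqn{e^{-dt/\tau}}, then a unit increment per spike. This is
#' the closed-form solution of the trace ODE between spikes, so the
#' discretization introduces no step-size bias. The adaptation potential
#' decays with `tau_adapt` and each of the neuron's own spikes lowers it by
#' `eta0`.
#'
#' @param trace_value current trace value (non-negative).
#' @param n_spikes 0 or 1, spike indicator for the bin.
#' @param dt bin width (ms).
#' @param tau trace time constant (ms).
#' @return Updated scalar (or vector, the functions are vectorized).
#' @export
#' @examples
#' decay_and_increment(0, 1, dt = 1, tau = 10)   # fresh spike -> unit amplitude
#' decay_and_increment(1, 0, dt = 1, tau = 10)   # exp(-0.1)
decay_and_increment <- function(trace_value, n_spikes, dt, tau) {
  if (any(dt <= 0)) stop("`dt` must be strictly positive")
  if (any(tau <= 0)) stop("`tau` must be strictly positive")
  stopifnot(all(n_spikes %in% c(0, 1)))
  trace_value * exp(-dt / tau) + n_spikes
}

#' @rdname decay_and_increment
#' @param eta_value current adaptation potential (mV, non-positive when
#'   started from rest).
#' @param own_spike 0 or 1, the neuron's own spike in the bin.
#' @param params a [neuron_params()].
#' @export
adaptation_step <- function(eta_value, own_spike, params) {
  stopifnot(inherits(params, "neuron_params"), all(own_spike %in% c(0, 1)))
  eta_value * exp(-params$dt / params$tau_adapt) - params$eta0 * own_spike
}

#' Membrane potential of one neuron
#'
#' Sum of weighted presynaptic EPSP traces plus the neuron's adaptation
#' potential: \eqn{u_i = \sum_j w_{ij}\phi_j + \eta_i}.
#'
#' @param weights_row synaptic weights onto the neuron (mV per unit EPSP).
#' @param phi presynaptic EPSP traces, same length.
#' @param eta adaptation potential (mV).
#' @return Membrane potential in mV.
#' @export
membrane_potential <- function(weights_row, phi, eta) {
  if (length(weights_row) != length(phi)) {
    stop("`weights_row` and `phi` must have equal length")
  }
  sum(weights_row * phi) + eta
}

#' Conditional firing intensity (exponential escape rate)
#'
#' \eqn{\rho(u) = \rho_0 \exp[(u - \vartheta)/\Delta u]}. The exponent is
#' clipped to +/-500 before exponentiation as overflow protection; the clip
#' is far outside any simulated regime.
#'
#' @param u membrane potential (mV), scalar or vector.
#' @param params a [neuron_params()].
#' @return Intensity in kHz, strictly positive and increasing in `u`.
#' @export
firing_intensity <- function(u, params) {
  stopifnot(inherits(params, "neuron_params"))
  if (any(!is.finite(u))) stop("`u` must be finite")
  z <- (u - params$theta) / params$delta_u
  params$rho0 * exp(pmin(pmax(z, -500), 500))
}

#' Finite-bin spike probability
#'
#' The probability of at least one event of a Poisson process with intensity
#' `rho` inside a bin of width `dt`: \eqn{1 - e^{-\rho\,dt}}. This is the
#' exact Bernoulli probability used by the sampler; it agrees with the
#' first-order approximation \eqn{\rho\,dt} for small \eqn{\rho\,dt}.
#'
#' @param rho intensity (kHz), non-negative.
#' @param dt bin width (ms).
#' @return Probability in `[0, 1)`.
#' @export
spike_probability <- function(rho, dt) {
  if (any(rho < 0)) stop("`rho` must be non-negative")
  if (any(dt <= 0)) stop("`dt` must be strictly positive")
  -expm1(-dt * rho)
}

# Intensities for a whole population from a trace state.
# Returns list(u, rho): vectors over neurons.
.population_intensity <- function(w, phi, eta, params) {
  u <- as.vector(w %*% phi) + eta
  z <- pmin(pmax((u - params$theta) / params$delta_u, -500), 500)
  list(u = u, rho = params$rho0 * exp(z))
}

#' Simulate the network
#'
#' Runs the discrete-time dynamics for `duration_bins` bins in one of three
#' modes:
#'
#' * `"generate"` — every neuron is sampled under the generative weights
#'   `w_g`; the result is a sample from the generative model (the
#'   recognition synapses are switched off).
#' * `"infer"` — the visible neurons are clamped bin-by-bin to `clamp`;
#'   hidden neurons are sampled under the recognition weights `w_q`
#'   (generative synapses switched off), yielding an approximate posterior
#'   sample of the hidden spike trains given the data.
#' * `"learn"` — identical dynamics to `"infer"`, but the generative-side
#'   potentials and intensities are additionally evaluated on the same spike
#'   history for every neuron, as required by the free-energy estimators and
#'   learning rules.
#'
#' Within each bin, potentials and intensities are computed from traces that
#' reflect spikes up to the *previous* bin; the bin's spikes then update the
#' traces with effect from the next bin, so a spike never influences its own
#' emission probability.
#'
#' @param net a [dual_network()].
#' @param mode `"generate"`, `"infer"` or `"learn"`.
#' @param duration_bins number of bins to simulate (ignored when `clamp`
#'   is given; the clamp duration is used).
#' @param clamp a [spike_raster()] over the visible neurons (required in
#'   `"infer"`/`"learn"`, forbidden in `"generate"`).
#' @param seed optional integer seed; identical seeds give identical traces.
#' @param init_state optional list with elements `phi` and `eta` to carry
#'   trace state over from a previous window (e.g. consecutive batches of
#'   one continuous trajectory); defaults to zero initial traces.
#' @return An object of class `network_trace`: the sampled/clamped raster
#'   plus per-neuron per-bin arrays `phi`, `eta` and, depending on mode,
#'   `u_g`/`rho_g` and `u_q`/`rho_q`, along with the final trace state in
#'   `$state`.
#' @export
run_network <- function(net, mode = c("generate", "infer", "learn"),
                        duration_bins = NULL, clamp = NULL, seed = NULL,
                        init_state = NULL) {
  mode <- match.arg(mode)
  validate_network(net)
  p <- net$params
  nv <- net$n_visible; nh <- net$n_hidden; n <- nv + nh
  if (mode == "generate") {
    if (!is.null(clamp)) stop("`clamp` is not allowed in generate mode")
    if (is.null(duration_bins) || duration_bins <= 0) {
      stop("`duration_bins` must be a positive count")
    }
    B <- as.integer(duration_bins)
  } else {
    if (is.null(clamp)) stop("modes 'infer' and 'learn' require a visible clamp")
    stopifnot(inherits(clamp, "spike_raster"))
    if (n_neurons(clamp) != nv) {
      stop("clamp must cover exactly the ", nv, " visible neurons")
    }
    if (abs(clamp$dt - p$dt) > 1e-12) stop("clamp bin width differs from the network's dt")
    B <- n_bins(clamp)
    if (!is.null(duration_bins) && duration_bins != B) {
      stop("`duration_bins` conflicts with the clamp duration")
    }
  }
  if (!is.null(seed)) set.seed(seed)

  decay_m <- exp(-p$dt / p$tau)
  decay_a <- exp(-p$dt / p$tau_adapt)
  phi <- rep(0, n); eta <- rep(0, n)
  if (!is.null(init_state)) {
    stopifnot(length(init_state$phi) == n, length(init_state$eta) == n)
    phi <- as.numeric(init_state$phi); eta <- as.numeric(init_state$eta)
  }

  X <- matrix(0L, n, B)
  PHI <- matrix(0, n, B); ETA <- matrix(0, n, B)
  need_g <- mode %in% c("generate", "learn")
  need_q <- mode %in% c("infer", "learn")
  UG <- if (need_g) matrix(0, n, B) else NULL
  RG <- if (need_g) matrix(0, n, B) else NULL
  UQ <- if (need_q) matrix(0, n, B) else NULL
  RQ <- if (need_q) matrix(0, n, B) else NULL
  hid <- if (nh > 0) nv + seq_len(nh) else integer(0)

  for (t in seq_len(B)) {
    PHI[, t] <- phi; ETA[, t] <- eta
    if (need_g) {
      g <- .population_intensity(net$w_g, phi, eta, p)
      UG[, t] <- g$u; RG[, t] <- g$rho
    }
    if (need_q) {
      q <- .population_intensity(net$w_q, phi, eta, p)
      UQ[, t] <- q$u; RQ[, t] <- q$rho
    }
    x <- integer(n)
    if (mode == "generate") {
      x <- as.integer(stats::runif(n) < -expm1(-p$dt * g$rho))
    } else {
      x[seq_len(nv)] <- clamp$spikes[, t]
      if (nh > 0) {
        x[hid] <- as.integer(stats::runif(nh) < -expm1(-p$dt * q$rho[hid]))
      }
    }
    X[, t] <- x
    phi <- phi * decay_m + x
    eta <- eta * decay_a - p$eta0 * x
  }

  structure(
    list(raster = spike_raster(X, dt = p$dt),
         phi = PHI, eta = ETA,
         u_g = UG, rho_g = RG, u_q = UQ, rho_q = RQ,
         n_visible = nv, n_hidden = nh, mode = mode, params = p,
         state = list(phi = phi, eta = eta)),
    class = "network_trace"
  )
}

#' @export
print.network_trace <- function(x, ...) {
  cat(sprintf("network_trace (%s mode): %d neurons (%d visible) x %d bins\n",
              x$mode, x$n_visible + x$n_hidden, x$n_visible, n_bins(x$raster)))
  invisible(x)
}

# Deterministic re-evaluation of traces and intensities for a *given* full
# raster (no sampling). Used by likelihood evaluation, finite differences and
# the enumeration oracle.
trace_given_raster <- function(net, raster, init_state = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  p <- net$params
  n <- net$n_visible + net$n_hidden
  if (n_neurons(raster) != n) stop("raster must cover the full population")
  B <- n_bins(raster)
  decay_m <- exp(-p$dt / p$tau)
  decay_a <- exp(-p$dt / p$tau_adapt)
  phi <- rep(0, n); eta <- rep(0, n)
  if (!is.null(init_state)) {
    phi <- as.numeric(init_state$phi); eta <- as.numeric(init_state$eta)
  }
  PHI <- matrix(0, n, B); ETA <- matrix(0, n, B)
  for (t in seq_len(B)) {
    PHI[, t] <- phi; ETA[, t] <- eta
    x <- raster$spikes[, t]
    phi <- phi * decay_m + x
    eta <- eta * decay_a - p$eta0 * x
  }
  UG <- net$w_g %*% PHI + ETA
  UQ <- net$w_q %*% PHI + ETA
  clipexp <- function(u) p$rho0 * exp(pmin(pmax((u - p$theta) / p$delta_u, -500), 500))
  structure(
    list(raster = raster, phi = PHI, eta = ETA,
         u_g = UG, rho_g = clipexp(UG), u_q = UQ, rho_q = clipexp(UQ),
         n_visible = net$n_visible, n_hidden = net$n_hidden,
         mode = "learn", params = p,
         state = list(phi = phi, eta = eta)),
    class = "network_trace"
  )
}
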