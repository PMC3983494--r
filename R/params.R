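#' Neuron parameters of the stochastic Spike Response Model
#'
#' Bundles the physical constants of the discrete-time Spike Response Model
#' with exponential escape noise. A neuron's membrane potential is the sum of
#' synaptically weighted EPSP traces and a spike-triggered adaptation
#' potential; spikes are emitted by an inhomogeneous Bernoulli process whose
#' per-bin probability derives from the conditional intensity
#' \eqn{\rho(t) = \rho_0 \exp[(u(t) - \vartheta)/\Delta u]}.
#'
#' Defaults are the simulation constants used throughout the package's
#' benchmarks: 1 ms bins, 10 ms membrane and adaptation time constants,
#' 0.1 mV adaptation strength, 1 kHz rate scale, 0 mV threshold and 1 mV
#' firing sensitivity.
#'
#' @param dt time-bin width (ms).
#' @param tau membrane / EPSP time constant (ms).
#' @param eta0 adaptation potential strength (mV); each spike hyperpolarizes
#'   the emitting neuron by this amount.
#' @param tau_adapt adaptation time constant (ms).
#' @param rho0 firing-rate scale (kHz), the intensity at threshold.
#' @param theta firing threshold (mV).
#' @param delta_u firing sensitivity (mV); smaller values make firing more
#'   deterministic in the membrane potential.
#'
#' @return An object of class `neuron_params`.
#' @export
#' @examples
#' p <- neuron_params()
#' firing_intensity(0, p)  # at threshold the intensity equals rho0
neuron_params <- function(dt = 1, tau = 10, eta0 = 0.1, tau_adapt = 10,
                          rho0 = 1, theta = 0, delta_u = 1) {
  stopifnot(
    is.numeric(dt), length(dt) == 1L, is.finite(dt),
    is.numeric(tau), length(tau) == 1L, is.finite(tau),
    is.numeric(tau_adapt), length(tau_adapt) == 1L, is.finite(tau_adapt),
    is.numeric(rho0), length(rho0) == 1L, is.finite(rho0),
    is.numeric(delta_u), length(delta_u) == 1L, is.finite(delta_u),
    is.numeric(eta0), length(eta0) == 1L, is.finite(eta0),
    is.numeric(theta), length(theta) == 1L, is.finite(theta)
  )
  if (dt <= 0) stop("`dt` must be strictly positive")
  if (tau <= 0) stop("`tau` must be strictly positive")
  if (tau_adapt <= 0) stop("`tau_adapt` must be strictly positive")
  if (rho0 <= 0) stop("`rho0` must be strictly positive")
  if (delta_u <= 0) stop("`delta_u` must be strictly positive")
  structure(
    list(dt = dt, tau = tau, eta0 = eta0, tau_adapt = tau_adapt,
         rho0 = rho0, theta = theta, delta_u = delta_u),
    class = "neuron_params"
  )
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Spike Response Model parameters:\n")
  cat(sprintf("  dt = %g ms, tau = %g ms, tau_adapt = %g ms\n",
              x$dt, x$tau, x$tau_adapt))
  cat(sprintf("  eta0 = %g mV, rho0 = %g kHz, theta = %g mV, delta_u = %g mV\n",
              x$eta0, x$rho0, x$theta, x$delta_u))
  invisible(x)
}

#' Read or write neuron parameters as a JSON configuration
#'
#' The JSON document has one key per [neuron_params()] field; missing keys
#' fall back to the package defaults.
#'
#' @param path file path of the JSON document.
#' @param params a `neuron_params` object (for writing).
#' @return `read_params_json()` returns a `neuron_params` object;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(neuron_params))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) {
    stop("unknown parameter field(s) in config: ", paste(extra, collapse = ", "))
  }
  do.call(neuron_params, cfg[intersect(names(cfg), known)])
}

#' @rdname read_params_json
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "neuron_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
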