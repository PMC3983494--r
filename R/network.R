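#' Recurrent spiking network with generative and recognition synapse sets
#'
#' A single population of Spike Response Model neurons, partitioned into
#' `n_visible` neurons that can be clamped to data and `n_hidden` latent
#' neurons, carries two weight matrices over the same somata:
#'
#' * `w_g` — the generative network, defining the joint point-process
#'   distribution over all spike trains;
#' * `w_q` — the recognition network, whose dynamics with the visible
#'   neurons clamped approximate the posterior over hidden spike trains.
#'
#' Both matrices are post-synaptic x pre-synaptic (entry `[i, j]` is the
#' contribution, in mV per unit EPSP, of neuron `j` onto neuron `i`).
#' Recognition synapses never target visible neurons: visible rows of `w_q`
#' are structurally zero. Self-connections are excluded on both matrices;
#' a neuron influences itself only through its adaptation potential.
#'
#' Neurons are ordered visible first, then hidden.
#'
#' @param n_visible,n_hidden neuron counts (hidden may be 0).
#' @param params a [neuron_params()] object shared by the whole population.
#' @param w_g,w_q optional weight matrices; when omitted they are drawn
#'   i.i.d. Gaussian with mean 0 and standard deviation `init_sd`, then
#'   masked to the legal topology.
#' @param init_sd standard deviation for random initial weights (mV).
#' @param seed optional integer seed for the random initialization.
#' @return An object of class `dual_network`.
#' @export
#' @examples
#' net <- dual_network(3, 2, seed = 1)
#' all(net$w_q[visible_idx(net), ] == 0)
dual_network <- function(n_visible, n_hidden, params = neuron_params(),
                         w_g = NULL, w_q = NULL, init_sd = 0.01, seed = NULL) {
  stopifnot(n_visible >= 1, n_hidden >= 0, inherits(params, "neuron_params"))
  n <- n_visible + n_hidden
  if (!is.null(seed)) set.seed(seed)
  if (is.null(w_g)) w_g <- matrix(stats::rnorm(n * n, sd = init_sd), n, n)
  if (is.null(w_q)) w_q <- matrix(stats::rnorm(n * n, sd = init_sd), n, n)
  w_g <- as.matrix(w_g); w_q <- as.matrix(w_q)
  if (!all(dim(w_g) == c(n, n)) || !all(dim(w_q) == c(n, n))) {
    stop("weight matrices must be ", n, " x ", n)
  }
  diag(w_g) <- 0
  diag(w_q) <- 0
  if (n_visible > 0) w_q[seq_len(n_visible), ] <- 0
  net <- structure(
    list(n_visible = as.integer(n_visible), n_hidden = as.integer(n_hidden),
         params = params, w_g = w_g, w_q = w_q),
    class = "dual_network"
  )
  validate_network(net)
  net
}

#' @rdname dual_network
#' @param net a `dual_network`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "dual_network"))
  n <- net$n_visible + net$n_hidden
  if (!all(is.finite(net$w_g)) || !all(is.finite(net$w_q))) {
    stop("weight matrices must be finite")
  }
  if (any(diag(net$w_g) != 0) || any(diag(net$w_q) != 0)) {
    stop("self-connections are not allowed (diagonal must be zero)")
  }
  if (net$n_visible > 0 && any(net$w_q[seq_len(net$n_visible), ] != 0)) {
    stop("recognition synapses onto visible neurons must be zero")
  }
  invisible(net)
}

#' @rdname dual_network
#' @export
visible_idx <- function(net) seq_len(net$n_visible)

#' @rdname dual_network
#' @export
hidden_idx <- function(net) {
  if (net$n_hidden == 0) integer(0) else net$n_visible + seq_len(net$n_hidden)
}

#' @export
print.dual_network <- function(x, ...) {
  cat(sprintf("dual_network: %d visible + %d hidden neurons\n",
              x$n_visible, x$n_hidden))
  cat(sprintf("  |w_g| rms = %.4g mV, |w_q| rms (hidden rows) = %.4g mV\n",
              sqrt(mean(x$w_g^2)),
              if (x$n_hidden > 0) sqrt(mean(x$w_q[hidden_idx(x), ]^2)) else 0))
  invisible(x)
}

# Mask of structurally allowed synapses for one weight set (logical matrix).
topology_mask <- function(net, which = c("G", "Q")) {
  which <- match.arg(which)
  n <- net$n_visible + net$n_hidden
  m <- matrix(TRUE, n, n)
  diag(m) <- FALSE
  if (which == "Q" && net$n_visible > 0) m[seq_len(net$n_visible), ] <- FALSE
  m
}
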