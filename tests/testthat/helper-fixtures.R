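# Shared fixtures: tiny networks and rasters built in code.

tiny_net <- function(n_visible = 2, n_hidden = 2, seed = 1, init_sd = 0.01,
                     params = neuron_params()) {
  dual_network(n_visible, n_hidden, params = params, init_sd = init_sd,
               seed = seed)
}

tiny_clamp <- function(n_visible = 2, n_bins = 4, rate = 0.3, seed = 5) {
  poisson_raster(rep(rate, n_visible), n_bins, seed = seed)
}

# All rasters of an n-neuron, B-bin window, as a list of 0/1 matrices.
all_rasters <- function(n, B) {
  k <- n * B
  lapply(seq_len(2^k) - 1L, function(code) {
    matrix(as.integer(intToBits(code)[seq_len(k)]), n, B)
  })
}

# Central finite differences of f over the entries of a weight matrix,
# restricted to a logical mask.
fd_gradient <- function(f, w, mask, h = 1e-5) {
  g <- matrix(0, nrow(w), ncol(w))
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w))) {
    if (!mask[i, j]) next
    wp <- w; wp[i, j] <- wp[i, j] + h
    wm <- w; wm[i, j] <- wm[i, j] - h
    g[i, j] <- (f(wp) - f(wm)) / (2 * h)
  }
  g
}
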