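#' Binary spike raster
#'
#' A spike raster stores at most one spike per neuron per time bin, the
#' discretization under which the network's point-process likelihood is
#' defined. Bins are half-open intervals `[t, t + dt)` indexed from 0, so a
#' spike in column `k` of the matrix occurred at time `(k - 1) * dt` ms.
#'
#' @param spikes binary matrix, neurons in rows, time bins in columns.
#' @param dt bin width (ms).
#' @param neuron_ids optional ordered labels; defaults to `0:(n-1)`.
#' @return An object of class `spike_raster`: a list with elements `spikes`
#'   (integer matrix), `dt` and `neuron_ids`.
#' @export
#' @examples
#' r <- spike_raster(matrix(c(0, 1, 0, 1, 0, 0), nrow = 2), dt = 1)
#' n_neurons(r); n_bins(r)
spike_raster <- function(spikes, dt = 1, neuron_ids = NULL) {
  if (!is.matrix(spikes)) spikes <- matrix(spikes, nrow = NROW(spikes))
  if (!all(spikes %in% c(0, 1))) {
    stop("raster entries must be 0 or 1 (at most one spike per bin)")
  }
  if (dt <= 0) stop("`dt` must be strictly positive")
  storage.mode(spikes) <- "integer"
  if (is.null(neuron_ids)) neuron_ids <- seq_len(nrow(spikes)) - 1L
  if (length(neuron_ids) != nrow(spikes)) {
    stop("`neuron_ids` length must match the number of raster rows")
  }
  structure(list(spikes = spikes, dt = dt, neuron_ids = neuron_ids),
            class = "spike_raster")
}

#' @rdname spike_raster
#' @param x a `spike_raster`.
#' @export
n_neurons <- function(x) nrow(x$spikes)

#' @rdname spike_raster
#' @export
n_bins <- function(x) ncol(x$spikes)

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d neurons x %d bins (dt = %g ms), %d spikes\n",
              n_neurons(x), n_bins(x), x$dt, sum(x$spikes)))
  invisible(x)
}

#' Raster input/output
#'
#' Two interchangeable on-disk representations are supported. The event-list
#' form is a TSV file with columns `neuron_id` (0-based) and `time_ms`
#' (bin-aligned spike times); raster dimensions and bin width travel in `#`
#' comment lines so that silent neurons and total duration survive the round
#' trip. The dense form is a compressed serialized container holding the full
#' binary matrix with its attributes. Both round-trip losslessly.
#'
#' @param raster a [spike_raster()].
#' @param path output/input file path.
#' @return Readers return a `spike_raster`; writers return `path` invisibly.
#' @export
write_events_tsv <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_neurons=%d", n_neurons(raster)),
    sprintf("# n_bins=%d", n_bins(raster)),
    sprintf("# dt=%.17g", raster$dt),
    sprintf("# neuron_ids=%s", paste(raster$neuron_ids, collapse = ",")),
    "neuron_id\ttime_ms"
  ), con)
  idx <- which(raster$spikes == 1L, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    ord <- order(idx[, "col"], idx[, "row"])
    idx <- idx[ord, , drop = FALSE]
    lines <- sprintf("%s\t%.17g",
                     raster$neuron_ids[idx[, "row"]],
                     (idx[, "col"] - 1L) * raster$dt)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  header <- readLines(path, n = 4L)
  meta <- function(key) sub(sprintf("^# %s=", key), "", grep(sprintf("^# %s=", key), header, value = TRUE))
  nn <- as.integer(meta("n_neurons"))
  nb <- as.integer(meta("n_bins"))
  dt <- as.numeric(meta("dt"))
  ids <- strsplit(meta("neuron_ids"), ",")[[1]]
  ids_num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(ids_num)) ids <- if (all(ids_num == round(ids_num))) as.integer(ids_num) else ids_num
  if (length(nn) != 1L || length(nb) != 1L || length(dt) != 1L) {
    stop("malformed event-list header in ", path)
  }
  ev <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          colClasses = c("character", "numeric"))
  spikes <- matrix(0L, nrow = nn, ncol = nb)
  if (nrow(ev) > 0L) {
    row <- match(ev$neuron_id, as.character(ids))
    col <- as.integer(round(ev$time_ms / dt)) + 1L
    if (anyNA(row)) stop("event list references unknown neuron ids")
    if (any(col < 1L | col > nb)) stop("event list contains out-of-range spike times")
    if (any(abs(ev$time_ms - (col - 1L) * dt) > 1e-9 * max(1, dt))) {
      stop("spike times are not aligned to the bin grid")
    }
    spikes[cbind(row, col)] <- 1L
  }
  spike_raster(spikes, dt = dt, neuron_ids = ids)
}

#' @rdname write_events_tsv
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  saveRDS(raster, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_raster <- function(path) {
  r <- readRDS(path)
  if (!inherits(r, "spike_raster")) stop("file does not contain a spike_raster")
  r
}

#' Independent-Poisson spike raster
#'
#' Samples every neuron independently in every bin with the exact finite-bin
#' spike probability \eqn{1 - e^{-\rho\,dt}} for its target rate.
#'
#' @param rates vector of rates, one per neuron (kHz).
#' @param duration_bins number of time bins.
#' @param dt bin width (ms).
#' @param seed optional integer seed.
#' @return A [spike_raster()].
#' @export
poisson_raster <- function(rates, duration_bins, dt = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(rates >= 0), duration_bins >= 1)
  p <- -expm1(-rates * dt)
  spikes <- matrix(stats::runif(length(rates) * duration_bins) <
                     rep(p, times = duration_bins),
                   nrow = length(rates))
  spike_raster(spikes + 0L, dt = dt)
}
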