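# Synthetic benchmark generators: sequential "stairs" spike patterns and a
# maze environment whose rooms are rate-coded images.

#' Stairs-pattern configuration
#'
#' The stairs benchmark drives groups of visible neurons in a fixed cyclic
#' order (1 -> 2 -> ... -> 1): the active group fires as a Poisson process
#' at `rate_high`, all other groups at `rate_low`, and each activation
#' lasts a random duration drawn from a Gaussian truncated at positive
#' values. Defaults: 3 groups of 10 neurons, 700 Hz / 1 Hz rates, dwell
#' times of mean 30 ms and SD 10 ms. The task requires memory roughly three
#' times the membrane time constant plus the group transition structure,
#' which is what makes it hard for a fully observed network.
#'
#' @param n_groups number of sequentially active groups.
#' @param group_size visible neurons per group.
#' @param rate_high,rate_low firing rates (kHz) of active/inactive groups.
#' @param duration_mean,duration_sd parameters (ms) of the truncated
#'   Gaussian activation duration.
#' @return An object of class `stairs_config`.
#' @export
stairs_config <- function(n_groups = 3, group_size = 10, rate_high = 0.7,
                          rate_low = 0.001, duration_mean = 30,
                          duration_sd = 10) {
  stopifnot(n_groups >= 1, group_size >= 1,
            rate_high >= 0, rate_low >= 0,
            duration_mean > 0, duration_sd >= 0)
  structure(list(n_groups = n_groups, group_size = group_size,
                 rate_high = rate_high, rate_low = rate_low,
                 duration_mean = duration_mean, duration_sd = duration_sd),
            class = "stairs_config")
}

# Gaussian truncated at positive values, sampled by rejection.
rtrunc_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw > 0])
  }
  out[seq_len(n)]
}

#' Generate a stairs-pattern spike raster
#'
#' @param cfg a [stairs_config()].
#' @param duration_bins number of time bins to generate.
#' @param dt bin width (ms).
#' @param seed optional integer seed.
#' @return A [spike_raster()] with `n_groups * group_size` neurons. Spike
#'   sampling uses the exact finite-bin probability
#'   \eqn{1 - e^{-\rho\,dt}}, so the 700 Hz "high" rate yields about a 0.50
#'   per-bin spike probability at 1 ms bins rather than a saturated one.
#' @export
stairs_raster <- function(cfg, duration_bins, dt = 1, seed = NULL) {
  stopifnot(inherits(cfg, "stairs_config"), duration_bins >= 1, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  total_ms <- duration_bins * dt
  # activation schedule: cyclic group order, truncated-Gaussian dwell times
  times <- numeric(0)
  while (sum(times) < total_ms) {
    times <- c(times, rtrunc_pos(16L, cfg$duration_mean, cfg$duration_sd))
  }
  bounds <- cumsum(times)
  bin_start <- (seq_len(duration_bins) - 1) * dt
  seg <- findInterval(bin_start, bounds) # 0-based segment index
  active_group <- (seg %% cfg$n_groups) + 1L

  n <- cfg$n_groups * cfg$group_size
  group_of <- rep(seq_len(cfg$n_groups), each = cfg$group_size)
  p_high <- -expm1(-cfg$rate_high * dt)
  p_low <- -expm1(-cfg$rate_low * dt)
  P <- matrix(p_low, n, duration_bins)
  for (g in seq_len(cfg$n_groups)) {
    P[group_of == g, active_group == g] <- p_high
  }
  spikes <- (matrix(stats::runif(n * duration_bins), n, duration_bins) < P) + 0L
  spike_raster(spikes, dt = dt)
}

#' Maze-environment configuration
#'
#' A square lattice of rooms; only lattice neighbors are mutually
#' accessible. Each room presents a grayscale "view" image whose pixels are
#' converted to firing rates by an affine map onto `rate_range`. The test
#' maze is the target maze with `n_replaced_rooms` randomly chosen rooms
#' given fresh images, so the two environments differ only there. Time
#' advances in abstract steps of `step_ms` (default 100 ms), one raster bin
#' per step.
#'
#' @param grid_side rooms per lattice side (default 4, i.e. 16 rooms).
#' @param image_shape integer vector of length 2, the room-view image size
#'   in pixels (default 28 x 28).
#' @param rate_range two rates in Hz to which pixel values 0 and 1 map.
#' @param n_replaced_rooms rooms replaced in the test maze.
#' @param step_ms duration (ms) represented by one time step.
#' @param dwell_mean mean number of consecutive steps spent in a room
#'   (geometric dwell times); 1 means the agent moves every step.
#' @return An object of class `maze_config`.
#' @export
maze_config <- function(grid_side = 4, image_shape = c(28, 28),
                        rate_range = c(0.01, 9), n_replaced_rooms = 3,
                        step_ms = 100, dwell_mean = 5) {
  stopifnot(grid_side >= 2, length(image_shape) == 2, all(image_shape >= 2),
            length(rate_range) == 2, all(rate_range >= 0),
            rate_range[2] > rate_range[1], step_ms > 0, dwell_mean >= 1)
  if (n_replaced_rooms >= grid_side^2) {
    stop("`n_replaced_rooms` must be smaller than the number of rooms")
  }
  structure(list(grid_side = as.integer(grid_side),
                 image_shape = as.integer(image_shape),
                 rate_range = rate_range,
                 n_replaced_rooms = as.integer(n_replaced_rooms),
                 step_ms = step_ms, dwell_mean = dwell_mean),
            class = "maze_config")
}

# Procedural glyph: a few random smoothed strokes on a pixel grid,
# normalized to span [0, 1] and rescaled to a common mean brightness so
# that maze rooms differ in *which* pixels are bright, not in how many —
# otherwise overall image brightness confounds the free-energy comparison
# between rooms. A seeded stand-in for external digit images so the
# benchmarks need no downloads.
glyph_image <- function(shape, mean_brightness = 0.2) {
  h <- shape[1]; w <- shape[2]
  img <- matrix(0, h, w)
  n_strokes <- sample(2:4, 1)
  for (s in seq_len(n_strokes)) {
    p0 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    p1 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    steps <- max(h, w) * 3L
    tt <- seq(0, 1, length.out = steps)
    rr <- pmin(pmax(round(p0[1] + tt * (p1[1] - p0[1])), 1), h)
    cc <- pmin(pmax(round(p0[2] + tt * (p1[2] - p0[2])), 1), w)
    img[cbind(rr, cc)] <- 1
  }
  # 3x3 box blur for stroke thickness
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- img
  sm <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    sm <- sm + pad[dr + seq_len(h), dc + seq_len(w)]
  }
  rng <- range(sm)
  img <- (sm - rng[1]) / (rng[2] - rng[1])
  for (k in 1:4) img <- pmin(img * (mean_brightness / mean(img)), 1)
  img
}

#' Affine pixel-to-rate map
#'
#' Maps pixel values in `[0, 1]` linearly onto `rate_range` (Hz); an image
#' spanning the full pixel range attains both endpoints exactly.
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @param rate_range two rates in Hz.
#' @return Matrix of firing rates (Hz).
#' @export
pixels_to_rates <- function(img, rate_range) {
  stopifnot(all(img >= 0), all(img <= 1))
  rate_range[1] + img * (rate_range[2] - rate_range[1])
}

#' Build the target and test mazes
#'
#' @param cfg a [maze_config()].
#' @param seed integer seed.
#' @param room_images optional list of `grid_side^2 + n_replaced_rooms`
#'   externally supplied grayscale images in `[0, 1]` (e.g. handwritten
#'   digits); by default procedural glyphs are generated. Procedural
#'   replacement glyphs are redrawn until their pixel correlation with
#'   every target-maze view falls below `max_similarity`, so that the
#'   replaced rooms present genuinely novel views (a random small glyph
#'   can otherwise come out as a near-copy of a familiar one, making the
#'   novelty task ill-posed); user-supplied images are taken as given.
#' @param max_similarity similarity ceiling for procedural replacement
#'   views (Pearson correlation over pixels).
#' @return A list with elements `target` and `test` (objects of class
#'   `maze`: room images, rate maps and lattice size) and
#'   `replaced_rooms`, the indices of the rooms whose images differ.
#' @export
make_mazes <- function(cfg, seed = 1, room_images = NULL,
                       max_similarity = 0.5) {
  stopifnot(inherits(cfg, "maze_config"))
  set.seed(seed)
  n_rooms <- cfg$grid_side^2
  need <- n_rooms + cfg$n_replaced_rooms
  if (is.null(room_images)) {
    target_pool <- lapply(seq_len(n_rooms), function(i) glyph_image(cfg$image_shape))
    draw_novel <- function() {
      best <- NULL; best_sim <- Inf
      for (try in seq_len(50)) {
        cand <- glyph_image(cfg$image_shape)
        sim <- max(vapply(target_pool, function(t) {
          stats::cor(as.vector(cand), as.vector(t))
        }, numeric(1)))
        if (sim < best_sim) { best <- cand; best_sim <- sim }
        if (sim < max_similarity) break
      }
      best
    }
    room_images <- c(target_pool,
                     lapply(seq_len(cfg$n_replaced_rooms), function(i) draw_novel()))
  } else {
    stopifnot(length(room_images) >= need)
    room_images <- lapply(room_images[seq_len(need)], function(m) {
      stopifnot(all(dim(m) == cfg$image_shape))
      m
    })
  }
  target_imgs <- room_images[seq_len(n_rooms)]
  replaced <- sort(sample.int(n_rooms, cfg$n_replaced_rooms))
  test_imgs <- target_imgs
  test_imgs[replaced] <- room_images[n_rooms + seq_len(cfg$n_replaced_rooms)]
  mk <- function(imgs) {
    structure(list(grid_side = cfg$grid_side, images = imgs,
                   rates = lapply(imgs, pixels_to_rates, rate_range = cfg$rate_range),
                   cfg = cfg),
              class = "maze")
  }
  list(target = mk(target_imgs), test = mk(test_imgs), replaced_rooms = replaced)
}

#' @export
print.maze <- function(x, ...) {
  cat(sprintf("maze: %d x %d rooms, %d x %d pixel views, rates in [%g, %g] Hz\n",
              x$grid_side, x$grid_side, x$cfg$image_shape[1],
              x$cfg$image_shape[2], x$cfg$rate_range[1], x$cfg$rate_range[2]))
  invisible(x)
}

#' Lattice neighbors of a room
#'
#' Rooms are numbered column-major on the `grid_side` x `grid_side`
#' lattice; corner rooms have 2 neighbors, edge rooms 3, interior rooms 4.
#'
#' @param maze a `maze`.
#' @param room room index in `1:grid_side^2`.
#' @return Integer vector of accessible room indices.
#' @export
room_neighbors <- function(maze, room) {
  g <- maze$grid_side
  r <- (room - 1L) %% g + 1L
  c <- (room - 1L) %/% g + 1L
  nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
  keep <- nb[, 1] >= 1 & nb[, 1] <= g & nb[, 2] >= 1 & nb[, 2] <= g
  nb <- nb[keep, , drop = FALSE]
  as.integer((nb[, 2] - 1L) * g + nb[, 1])
}

#' Random walk over the maze lattice
#'
#' At each change-point the agent moves to a uniformly chosen neighboring
#' room (staying put is not a move); it then dwells there for a geometric
#' number of time steps with mean `dwell_mean` before moving again.
#'
#' @param maze a `maze`.
#' @param n_steps trajectory length in time steps.
#' @param seed optional integer seed.
#' @param start starting room (default: uniform random).
#' @param dwell_mean override of the maze's configured mean dwell time.
#' @return Integer vector of length `n_steps`: the room occupied at each
#'   time step.
#' @export
random_walk <- function(maze, n_steps, seed = NULL, start = NULL,
                        dwell_mean = maze$cfg$dwell_mean) {
  stopifnot(n_steps >= 1, dwell_mean >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_rooms <- maze$grid_side^2
  room <- if (is.null(start)) sample.int(n_rooms, 1) else as.integer(start)
  path <- integer(n_steps)
  t <- 1L
  while (t <= n_steps) {
    dwell <- 1L + stats::rgeom(1, prob = 1 / dwell_mean)
    stay <- min(dwell, n_steps - t + 1L)
    path[t:(t + stay - 1L)] <- room
    t <- t + stay
    nb <- room_neighbors(maze, room)
    room <- nb[sample.int(length(nb), 1)]
  }
  path
}

#' Convert a room trajectory into a visible spike raster
#'
#' At each time step the current room's rate image drives one pixel-neuron
#' per image pixel as independent Poisson samples over the step duration:
#' a pixel with rate \eqn{r} Hz spikes with probability
#' \eqn{1 - e^{-r \cdot \mathrm{step\_ms}/1000}}. One raster bin per step;
#' the raster's `dt` is 1 abstract unit.
#'
#' @param maze a `maze`.
#' @param path integer room sequence from [random_walk()].
#' @param seed optional integer seed.
#' @return A [spike_raster()] with `prod(image_shape)` neurons and
#'   `length(path)` bins.
#' @export
trajectory_to_raster <- function(maze, path, seed = NULL) {
  stopifnot(length(path) >= 1)
  if (!is.null(seed)) set.seed(seed)
  step_s <- maze$cfg$step_ms / 1000
  n_px <- prod(maze$cfg$image_shape)
  P <- vapply(path, function(room) {
    -expm1(-as.vector(maze$rates[[room]]) * step_s)
  }, numeric(n_px))
  spikes <- (matrix(stats::runif(length(P)), nrow = n_px) < P) + 0L
  spike_raster(spikes, dt = 1)
}

#' Serialize a maze as JSON
#'
#' Room images are stored as nested pixel arrays; adjacency is implied by
#' the lattice and not stored.
#'
#' @param maze a `maze`.
#' @param path output JSON file.
#' @return `read_maze_json()` returns a `maze`.
#' @export
write_maze_json <- function(maze, path) {
  doc <- list(grid_side = maze$grid_side,
              cfg = unclass(maze$cfg),
              images = maze$images)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maze_json
#' @export
read_maze_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(maze_config, doc$cfg[names(formals(maze_config))])
  # equal-shaped room images simplify to a rooms x height x width array
  imgs <- if (is.array(doc$images) && length(dim(doc$images)) == 3) {
    lapply(seq_len(dim(doc$images)[1]), function(i) {
      matrix(doc$images[i, , ], dim(doc$images)[2], dim(doc$images)[3])
    })
  } else {
    lapply(doc$images, function(m) {
      m <- as.matrix(m)
      dimnames(m) <- NULL
      m
    })
  }
  structure(list(grid_side = doc$grid_side, images = imgs,
                 rates = lapply(imgs, pixels_to_rates, rate_range = cfg$rate_range),
                 cfg = cfg),
            class = "maze")
}
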