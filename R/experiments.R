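# Experiment drivers: the training protocol, variant comparisons, and the
# maze novelty experiment.

#' Training protocol
#'
#' Organization of a training run: data arrives in batches of `batch_ms`
#' which are presented sequentially; `presentations_per_epoch` batches form
#' one epoch (the reference protocol uses 200 ms x 500 presentations =
#' 100 s of data per epoch); the marginal likelihood of held-out data is
#' estimated by importance sampling every `eval_every_epochs` epochs with
#' `eval_samples` hidden samples per `eval_sample_ms` window. The drivers
#' default to desk-scale counts; the reference protocol is restored by
#' `full_scale = TRUE`.
#'
#' @param n_epochs number of training epochs.
#' @param presentations_per_epoch data batches per epoch.
#' @param batch_ms batch window length (ms).
#' @param eval_every_epochs epochs between importance-sampling evaluations.
#' @param eval_samples,eval_sample_ms evaluation protocol.
#' @param full_scale if `TRUE`, override counts with the reference
#'   protocol (500 presentations per epoch, evaluation every 500 epochs,
#'   500 samples of 100 ms).
#' @return An object of class `training_protocol`.
#' @export
training_protocol <- function(n_epochs = 10, presentations_per_epoch = 50,
                              batch_ms = 200, eval_every_epochs = 5,
                              eval_samples = 200, eval_sample_ms = 100,
                              full_scale = FALSE) {
  if (full_scale) {
    presentations_per_epoch <- 500
    eval_every_epochs <- 500
    eval_samples <- 500
    eval_sample_ms <- 100
  }
  stopifnot(n_epochs >= 1, presentations_per_epoch >= 1, batch_ms > 0,
            eval_every_epochs >= 1, eval_samples >= 1, eval_sample_ms > 0)
  structure(list(n_epochs = as.integer(n_epochs),
                 presentations_per_epoch = as.integer(presentations_per_epoch),
                 batch_ms = batch_ms,
                 eval_every_epochs = as.integer(eval_every_epochs),
                 eval_samples = as.integer(eval_samples),
                 eval_sample_ms = eval_sample_ms),
            class = "training_protocol")
}

# Normalize a data source into function(batch_index) -> visible raster.
.as_batch_source <- function(data_source, batch_bins, n_visible, dt) {
  if (is.function(data_source)) return(data_source)
  if (inherits(data_source, "spike_raster")) {
    total <- n_bins(data_source)
    n_batches_avail <- total %/% batch_bins
    if (n_batches_avail < 1L) stop("data raster shorter than one batch")
    return(function(b) {
      k <- ((b - 1L) %% n_batches_avail)
      cols <- (k * batch_bins + 1L):((k + 1L) * batch_bins)
      spike_raster(data_source$spikes[, cols, drop = FALSE], dt = dt)
    })
  }
  if (is.list(data_source)) {
    m <- length(data_source)
    return(function(b) data_source[[((b - 1L) %% m) + 1L]])
  }
  stop("`data_source` must be a function, a spike_raster, or a list of rasters")
}

#' Train a network
#'
#' Runs the learn-mode loop of the selected rule variant over the batches
#' of the protocol, with the visible neurons driven exactly by the data:
#'
#' * `"fully_observed"` — maximum-likelihood gradient ascent on the
#'   generative weights (network must have no hidden neurons).
#' * `"naive_batch"` — free-energy descent with the unmodified
#'   score-function recognition gradient.
#' * `"vr_batch"` — as naive, with the free-energy baseline (moving
#'   average over previous batches) removed from the modulator.
#' * `"online"` — per-bin three-factor rule with Hebbian traces and the
#'   running novelty signal; weights change at every time step.
#' * `"simplified"` — merged network (recognition weights tied to the
#'   generative ones), visible-only free energy, per-bin updates.
#'
#' @param net a [dual_network()]; its weights are the initial condition.
#' @param data_source a function `f(batch_index)` returning a visible
#'   [spike_raster()] of one batch, a long raster (sliced and recycled), or
#'   a list of batch rasters (recycled).
#' @param protocol a [training_protocol()].
#' @param cfg a [learner_config()]; `cfg$variant` selects the rule.
#' @param eval_data optional held-out visible raster; when provided the
#'   marginal likelihood is estimated at epoch checkpoints.
#' @param seed optional integer seed for the whole run (data sampling from
#'   a function source included); identical seeds and configuration give
#'   identical logs.
#' @param carry_state carry EPSP/adaptation trace state across consecutive
#'   batches (use when batches are slices of one continuous trajectory);
#'   default `FALSE` resets traces at each batch.
#' @param checkpoint_dir optional directory; when set, weights are saved at
#'   every evaluation checkpoint.
#' @return A list of class `training_run`: the trained `net`, a per-batch
#'   `log` data frame (`epoch`, `batch`, `f_hat`, `modulator`, weight
#'   norms), an `evals` data frame of checkpoint log-likelihood estimates,
#'   and the final learner state. If the weights diverge (non-finite
#'   values, a real failure mode of the unbaselined score-function rule),
#'   training halts with a warning at the last finite weights; the batch
#'   index is recorded in `diverged_at`.
#' @export
train <- function(net, data_source, protocol = training_protocol(),
                  cfg = learner_config(), eval_data = NULL, seed = NULL,
                  carry_state = FALSE, checkpoint_dir = NULL) {
  validate_network(net)
  stopifnot(inherits(protocol, "training_protocol"), inherits(cfg, "learner_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- net$params
  batch_bins <- as.integer(round(protocol$batch_ms / p$dt))
  source_fn <- .as_batch_source(data_source, batch_bins, net$n_visible, p$dt)
  variant <- cfg$variant
  if (variant == "fully_observed" && net$n_hidden > 0) {
    stop("the fully observed rule requires a network without hidden neurons")
  }
  n_batches <- protocol$n_epochs * protocol$presentations_per_epoch

  traces <- hebbian_traces(net, cfg$tau_g)
  tracker <- fe_tracker(cfg$tau_g, cfg$tau_baseline)
  baseline <- NA_real_
  state <- NULL
  if (variant == "simplified") net <- tie_recognition_weights(net)

  log_rows <- vector("list", n_batches)
  evals <- list()
  eval_now <- function(epoch, batch) {
    if (is.null(eval_data)) return(NULL)
    est <- estimate_log_likelihood(net, eval_data, protocol$eval_samples,
                                   protocol$eval_sample_ms)
    if (!is.null(checkpoint_dir)) {
      saveRDS(net, file.path(checkpoint_dir,
                             sprintf("checkpoint_epoch%04d.rds", epoch)))
    }
    data.frame(epoch = epoch, batch = batch,
               log_likelihood = est$log_likelihood, se = est$se)
  }

  diverged_at <- NA_integer_
  for (b in seq_len(n_batches)) {
    epoch <- ((b - 1L) %/% protocol$presentations_per_epoch) + 1L
    clamp <- source_fn(b)
    if (n_bins(clamp) != batch_bins) stop("data batch has the wrong duration")
    if (!carry_state) state <- NULL
    net_prev <- net

    if (variant %in% c("fully_observed", "naive_batch", "vr_batch")) {
      tr <- run_network(net, "learn", clamp = clamp, init_state = state)
      state <- tr$state
      if (variant == "fully_observed") {
        f_hat <- -complete_log_likelihood(tr, "G")
        mod <- 0
        net$w_g <- net$w_g + cfg$mu_g * fully_observed_gradient(tr)
      } else {
        f_hat <- free_energy_window(tr, form = cfg$learn_form)
        if (variant == "naive_batch") {
          mod <- f_hat
          upd <- naive_batch_update(tr, f_hat, cfg)
        } else if (b <= cfg$baseline_warmup) {
          # baseline not yet estimated: accumulate a plain running mean and
          # hold the recognition weights (the generative rule needs none)
          baseline <- if (is.na(baseline)) f_hat else
            baseline + (f_hat - baseline) / b
          mod <- 0
          upd <- naive_batch_update(tr, 0, cfg)
        } else {
          mod <- f_hat - baseline
          upd <- variance_reduced_update(tr, f_hat, baseline, cfg)
          baseline <- cfg$baseline_decay * baseline +
            (1 - cfg$baseline_decay) * f_hat
        }
        net$w_g <- net$w_g + upd$dw_g
        net$w_q <- net$w_q + upd$dw_q
      }
      e_last <- mod
    } else {
      # per-bin online variants
      res <- .online_batch(net, clamp, traces, tracker, cfg, variant, state)
      net <- res$net
      traces <- res$traces
      tracker <- res$tracker
      state <- res$state
      f_hat <- res$f_hat
      e_last <- res$e_last
      mod <- e_last
    }
    w_max <- max(abs(net$w_g), abs(net$w_q))
    if (!is.finite(w_max) || w_max > 100) {
      # score-function noise has blown the weights up (a real failure mode
      # of the unbaselined rule): keep the last sane weights, record the
      # diagnostic and halt without evaluating — a diverged model defines
      # no usable likelihood
      warning(sprintf("weights diverged at batch %d (max |w| = %g mV, F_hat = %g); halting",
                      b, w_max, f_hat))
      net <- net_prev
      diverged_at <- b
      break
    }
    log_rows[[b]] <- data.frame(
      epoch = epoch, batch = b, f_hat = f_hat, modulator = mod,
      w_g_norm = sqrt(mean(net$w_g^2)),
      w_q_norm = if (net$n_hidden > 0) sqrt(mean(net$w_q[hidden_idx(net), ]^2)) else 0)
    end_of_epoch <- (b %% protocol$presentations_per_epoch) == 0L
    if (end_of_epoch &&
        (epoch %% protocol$eval_every_epochs == 0L || epoch == protocol$n_epochs)) {
      ev <- eval_now(epoch, b)
      if (!is.null(ev)) evals[[length(evals) + 1L]] <- ev
    }
  }

  structure(
    list(net = net,
         log = do.call(rbind, log_rows),
         evals = if (length(evals)) do.call(rbind, evals) else
           data.frame(epoch = integer(), batch = integer(),
                      log_likelihood = numeric(), se = numeric()),
         learner_state = list(traces = traces, tracker = tracker,
                              baseline = baseline, trace_state = state),
         diverged_at = diverged_at,
         cfg = cfg, protocol = protocol),
    class = "training_run"
  )
}

# One batch of per-bin online learning ("online" or "simplified" variant).
# Simulates the recognition dynamics bin by bin under the *current* weights
# and applies the per-bin updates immediately.
.online_batch <- function(net, clamp, traces, tracker, cfg, variant, state) {
  p <- net$params
  nv <- net$n_visible; nh <- net$n_hidden; n <- nv + nh
  B <- n_bins(clamp)
  decay_m <- exp(-p$dt / p$tau)
  decay_a <- exp(-p$dt / p$tau_adapt)
  phi <- rep(0, n); eta <- rep(0, n)
  if (!is.null(state)) { phi <- state$phi; eta <- state$eta }
  hid <- if (nh > 0) nv + seq_len(nh) else integer(0)
  f_sum <- 0; e_last <- 0
  for (t in seq_len(B)) {
    g <- .population_intensity(net$w_g, phi, eta, p)
    if (variant == "simplified") net <- tie_recognition_weights(net)
    q <- .population_intensity(net$w_q, phi, eta, p)
    x <- integer(n)
    x[seq_len(nv)] <- clamp$spikes[, t]
    if (nh > 0) {
      x[hid] <- as.integer(stats::runif(nh) < -expm1(-p$dt * q$rho[hid]))
    }
    bin <- list(x = x, phi = phi, u_g = g$u, rho_g = g$rho,
                u_q = q$u, rho_q = q$rho, dt = p$dt)
    if (variant == "online") {
      st <- online_step(traces, bin, tracker, cfg)
      net$w_g <- net$w_g + st$dw_g
      net$w_q <- net$w_q + st$dw_q
    } else {
      st <- simplified_step(traces, bin, tracker, cfg)
      net$w_g <- net$w_g + st$dw
      net <- tie_recognition_weights(net)
    }
    traces <- st$traces
    tracker <- st$tracker
    f_sum <- f_sum + st$f_t
    e_last <- st$e_n
    phi <- phi * decay_m + x
    eta <- eta * decay_a - p$eta0 * x
  }
  list(net = net, traces = traces, tracker = tracker,
       state = list(phi = phi, eta = eta), f_hat = f_sum, e_last = e_last)
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf("training_run: %s variant, %d batches\n",
              x$cfg$variant, nrow(x$log)))
  if (nrow(x$evals) > 0) {
    last <- x$evals[nrow(x$evals), ]
    cat(sprintf("  final evaluation: log L = %.3f (SE %.3f) at epoch %d\n",
                last$log_likelihood, last$se, last$epoch))
  }
  invisible(x)
}

#' Write a training log as TSV
#'
#' @param run a `training_run`.
#' @param path output TSV path.
#' @export
write_training_log <- function(run, path) {
  utils::write.table(run$log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Train several rule variants on an identical data stream
#'
#' Each variant starts from the same initial weights and consumes the same
#' pre-drawn sequence of data batches, so checkpoint evaluations are paired
#' across variants.
#'
#' @param net a [dual_network()]; cloned as the common initial condition.
#' @param batches list of visible batch rasters (the shared data stream).
#' @param eval_data held-out visible raster for checkpoint evaluations.
#' @param variants character vector of rule variants (see [train()]).
#' @param protocol a [training_protocol()].
#' @param cfg base [learner_config()]; the variant field is overridden.
#' @param seed integer seed (shared across variants).
#' @return A list of class `variant_comparison`: `evals` (long data frame
#'   with a `variant` column), `final` (one row per variant) and the
#'   trained networks.
#' @export
compare_variants <- function(net, batches, eval_data,
                             variants = c("naive_batch", "vr_batch"),
                             protocol = training_protocol(),
                             cfg = learner_config(), seed = 1) {
  stopifnot(length(variants) >= 2)
  runs <- lapply(variants, function(v) {
    cfg_v <- cfg
    cfg_v$variant <- v
    train(net, batches, protocol, cfg_v, eval_data = eval_data, seed = seed)
  })
  names(runs) <- variants
  evals <- do.call(rbind, lapply(variants, function(v) {
    ev <- runs[[v]]$evals
    if (nrow(ev) > 0) ev$variant <- v
    ev
  }))
  final <- do.call(rbind, lapply(variants, function(v) {
    ev <- runs[[v]]$evals
    if (nrow(ev) == 0) {
      # diverged before the first checkpoint: no usable likelihood
      data.frame(epoch = NA_integer_, log_likelihood = -Inf, se = NA_real_)
    } else {
      ev[nrow(ev), c("epoch", "log_likelihood", "se")]
    }
  }))
  final$variant <- variants
  structure(list(evals = evals, final = final,
                 nets = lapply(runs, `[[`, "net"),
                 logs = lapply(runs, `[[`, "log")),
            class = "variant_comparison")
}

#' Epochs needed to reach a log-likelihood threshold
#'
#' Reads a checkpoint-evaluation table and returns the first epoch whose
#' estimate reaches `threshold`; `Inf` if it is never reached. Used to
#' quantify learning-speed ratios between rule variants.
#'
#' @param evals data frame with columns `epoch` and `log_likelihood`.
#' @param threshold log-likelihood threshold (nats).
#' @return Scalar epoch count (possibly `Inf`).
#' @export
epochs_to_threshold <- function(evals, threshold) {
  hit <- evals$epoch[evals$log_likelihood >= threshold]
  if (length(hit) == 0) Inf else min(hit)
}

#' Maze novelty experiment
#'
#' Trains a network online on random-walk trajectories through the target
#' maze and periodically probes both the target and the test maze with a
#' shared room trajectory: the probe records the mean free energy (the
#' slow-baseline analogue) and the fine-grained novelty signal
#' \eqn{e_N(t)} along the walk. Probing never updates the weights. Early in
#' learning the two mazes are indistinguishable; once the target maze is
#' learned, the test maze's replaced rooms drive the free energy and the
#' novelty signal up.
#'
#' @param maze_cfg a [maze_config()].
#' @param n_hidden hidden neurons of the agent network.
#' @param protocol a [training_protocol()]; batches are whole trajectories
#'   (one bin per time step), so `batch_ms` is interpreted in steps.
#' @param cfg a [learner_config()] (variant is forced to `"online"`).
#' @param probe_every_epochs epochs between probes.
#' @param probe_steps probe trajectory length (time steps).
#' @param probe_reps number of independent probe walks per probe point;
#'   probes report the mean free energy across walks (hidden-spike
#'   sampling makes single-walk estimates noisy).
#' @param probe_dwell mean dwell time (steps) of the final fine-grained
#'   probe walk; room visits must be long relative to the fast averaging
#'   time constant for the novelty signal to develop within a visit.
#' @param seed integer seed.
#' @return A list of class `novelty_experiment`: `probes` (epoch, walk
#'   rep, maze, mean free energy per step), `final_traces` (per-bin
#'   novelty traces on both mazes pooled over `probe_reps` shared
#'   trajectories, with walk, room and replaced-room annotation),
#'   `replaced_rooms`, the `mazes` and the trained `net`. Probe free
#'   energies use the discrete-exact likelihood form.
#' @export
novelty_experiment <- function(maze_cfg = maze_config(), n_hidden = 30,
                               protocol = training_protocol(),
                               cfg = learner_config(variant = "online"),
                               probe_every_epochs = 1, probe_steps = 100,
                               probe_reps = 4, probe_dwell = 20,
                               seed = 1) {
  set.seed(seed)
  mazes <- make_mazes(maze_cfg, seed = seed)
  n_px <- prod(maze_cfg$image_shape)
  steps_per_batch <- as.integer(round(protocol$batch_ms))
  net <- dual_network(n_px, n_hidden)
  cfg$variant <- "online"

  traces <- hebbian_traces(net, cfg$tau_g)
  tracker <- fe_tracker(cfg$tau_g, cfg$tau_baseline)
  n_batches <- protocol$n_epochs * protocol$presentations_per_epoch

  # Probes are likelihood evaluations, so they use the exactly normalized
  # discrete form; the continuous-limit form is not a probability at the
  # high intensities a partially trained recognition proposal can visit.
  probe <- function(epoch) {
    out <- lapply(seq_len(probe_reps), function(rep) {
      path <- random_walk(mazes$target, probe_steps)
      rows <- lapply(c("target", "test"), function(which) {
        r <- trajectory_to_raster(mazes[[which]], path)
        tr <- run_network(net, "learn", clamp = r)
        f <- instantaneous_free_energy(tr, "full", form = "discrete_exact")
        data.frame(epoch = epoch, rep = rep, maze = which, mean_f = mean(f))
      })
      do.call(rbind, rows)
    })
    do.call(rbind, out)
  }

  probes <- list(probe(0L))
  for (b in seq_len(n_batches)) {
    epoch <- ((b - 1L) %/% protocol$presentations_per_epoch) + 1L
    path <- random_walk(mazes$target, steps_per_batch)
    clamp <- trajectory_to_raster(mazes$target, path)
    res <- .online_batch(net, clamp, traces, tracker, cfg, "online", NULL)
    net <- res$net; traces <- res$traces; tracker <- res$tracker
    if (!all(is.finite(net$w_g)) || !all(is.finite(net$w_q))) {
      stop("weights diverged during novelty training at batch ", b)
    }
    if ((b %% protocol$presentations_per_epoch) == 0L &&
        (epoch %% probe_every_epochs == 0L || epoch == protocol$n_epochs)) {
      probes[[length(probes) + 1L]] <- probe(epoch)
    }
  }

  # Final fine-grained novelty traces, pooled over `probe_reps` slow shared
  # trajectories (a single walk visits too few rooms for stable segment
  # statistics). The tracker is warm-started at the *target* maze's mean
  # free energy on the same walk for both mazes: the agent carries the
  # background surprise level of the environment it has learned into the
  # altered one, so novelty in the replaced rooms shows as one-sided
  # positive excursions.
  final_traces <- do.call(rbind, lapply(seq_len(probe_reps), function(rep) {
    final_path <- random_walk(mazes$target, probe_steps,
                              dwell_mean = probe_dwell)
    f_by_maze <- lapply(c(target = "target", test = "test"), function(which) {
      r <- trajectory_to_raster(mazes[[which]], final_path)
      tr <- run_network(net, "learn", clamp = r)
      instantaneous_free_energy(tr, "full", form = "discrete_exact")
    })
    background <- mean(f_by_maze$target)
    do.call(rbind, lapply(c("target", "test"), function(which) {
      tk <- fe_tracker(cfg$tau_g, cfg$tau_baseline,
                       fast_init = background, slow_init = background)
      nt <- novelty_trace(f_by_maze[[which]], tk, dt = net$params$dt)
      nt$walk <- rep
      nt$maze <- which
      nt$room <- final_path
      nt$replaced <- final_path %in% mazes$replaced_rooms
      nt
    }))
  }))

  structure(list(probes = do.call(rbind, probes), final_traces = final_traces,
                 replaced_rooms = mazes$replaced_rooms, mazes = mazes,
                 net = net),
            class = "novelty_experiment")
}
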