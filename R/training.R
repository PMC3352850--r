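# Training protocol: concurrent unsupervised burst-STDP (shape and motion
# S2 layers), value-gated supervised learning (classifier pools and
# attention), periodic per-layer homeostatic renormalization ("sleep"), an
# annealed reward schedule, and final consolidation to binary synapses.

#' Training schedule
#'
#' @param n_presentations Single-object noiseless stimulus presentations per
#'   epoch (default 400, i.e. on average 50 per trajectory).
#' @param epochs Number of training epochs (default 1).
#' @param renorm_intervals Named list of per-layer renormalization ("sleep")
#'   intervals in ticks. Defaults: S2-shape-ex 500, CLA-shape 2500,
#'   S2-where-ex 500, CLA-where 2500, Attention 2500.
#' @param anneal_horizon Presentations over which the reward/punishment
#'   constants anneal (default one epoch's worth); passed to
#'   [reward_schedule()].
#' @param letters Letter pool presented during training.
#' @param train_noise Per-pixel flip probability applied to training
#'   frames (default 0; the unsupervised stage uses a small exploration
#'   noise so that winner-take-all races are not frozen by the otherwise
#'   fully deterministic rhythm -- see the methods vignette).
#' @param seed Integer seed controlling the training trial stream.
#'
#' @return An object of class `bn_training_schedule`.
#' @export
training_schedule <- function(n_presentations = 400L, epochs = 1L,
                              renorm_intervals = NULL,
                              anneal_horizon = n_presentations,
                              letters = c("T", "L", "J"), train_noise = 0,
                              seed = 1L) {
  stopifnot(n_presentations >= 0, epochs >= 1)
  default_iv <- list(
    `S2-shape-ex` = 500L, `CLA-shape` = 2500L,
    `S2-where-ex` = 500L, `CLA-where` = 2500L, Attention = 2500L
  )
  if (!is.null(renorm_intervals)) {
    default_iv[names(renorm_intervals)] <- renorm_intervals
  }
  structure(
    list(
      n_presentations = as.integer(n_presentations),
      epochs = as.integer(epochs),
      renorm_intervals = default_iv,
      anneal_horizon = as.integer(anneal_horizon),
      letters = letters, train_noise = train_noise, seed = as.integer(seed)
    ),
    class = "bn_training_schedule"
  )
}

#' Judge a network response against the trial's label
#'
#' The winning pool is the one with the largest spike count summed over the
#' trial window; the response is correct when the winning pool matches the
#' label. A tie between the top pools yields no reward event.
#'
#' @param spike_counts Per-neuron total spike counts of the judged group
#'   over the trial window.
#' @param pools Named list of pool index vectors.
#' @param true_label Name of the pool that should win.
#'
#' @return A list with `winner` (pool name or `NA` on a tie/total silence),
#'   `correct` (logical, `NA` if no event), and `event` (logical: whether a
#'   reward event occurred).
#' @export
#' @examples
#' judge_response(c(6, 6, 3, 1), list(a = 1:2, b = 3:4), "a")
judge_response <- function(spike_counts, pools, true_label) {
  sums <- vapply(pools, function(ix) sum(spike_counts[ix]), numeric(1))
  top <- max(sums)
  winners <- names(sums)[sums == top]
  if (top == 0 || length(winners) > 1) {
    return(list(winner = NA_character_, correct = NA, event = FALSE))
  }
  list(winner = winners, correct = winners == true_label, event = TRUE)
}

# Run one training presentation (single object, noiseless unless the trial
# says otherwise), applying unsupervised updates online, accumulating
# supervised eligibility, and renormalizing layers at their intervals.
# Returns per-group spike counts for the judged groups plus the supervised
# eligibility accumulators.
bn_train_trial <- function(net, trial, cfg, unsupervised = TRUE,
                           supervised = TRUE, test_dynamics = FALSE) {
  st <- bn_init_state(net, 1L)
  frames <- bn_trial_frames(trial)
  if (trial$noise_p > 0) {
    flips <- matrix(
      stats::runif(length(frames)) < trial$noise_p,
      nrow(frames), ncol(frames)
    )
    frames[flips] <- 1L - frames[flips]
  }

  conns <- net$conns
  unsup_idx <- which(vapply(conns, function(cn) cn$plastic && !cn$supervised, logical(1)))
  sup_idx <- which(vapply(conns, function(cn) cn$supervised, logical(1)))
  trace_groups <- names(net$groups)[vapply(net$groups, function(g) g$has_trace, logical(1))]

  acc <- lapply(conns[sup_idx], function(cn) cn$W * 0)
  names(acc) <- names(conns)[sup_idx]
  # window-integrated presynaptic traces, independent of postsynaptic
  # firing (teacher eligibility for silent label-pool neurons)
  acc_src <- lapply(conns[sup_idx], function(cn) {
    numeric(net$groups[[cn$source]]$n)
  })
  names(acc_src) <- names(acc)
  counts <- list(
    `CLA-shape` = numeric(net$groups[["CLA-shape"]]$n),
    `CLA-where` = numeric(net$groups[["CLA-where"]]$n),
    `CLA-where-late` = numeric(net$groups[["CLA-where"]]$n),
    Attention = numeric(net$groups[["Attention"]]$n)
  )
  # Arrival window: the last movement steps during which the object is still
  # substantially on the retina (it then slides out and the motion stream
  # falls silent).
  late_start <- trial$duration - (net$late_dwells + 2L) * trial$speed + 1L
  late_end <- trial$duration - 2L * trial$speed

  for (t in seq_len(trial$duration)) {
    spk <- bn_tick(net, st, frames[, t], testing = test_dynamics)
    for (gn in trace_groups) {
      b <- st$traces[[gn]] + cfg$trace_increment * spk[[gn]] - cfg$trace_decay
      b[b < 0] <- 0
      st$traces[[gn]] <- b
    }
    if (unsupervised) {
      for (ci in unsup_idx) {
        cn <- net$conns[[ci]]
        post <- spk[[cn$target]][, 1]
        if (any(post > 0)) {
          net$conns[[ci]]$W <- burst_stdp_update(
            cn$W, st$traces[[cn$source]][, 1], post,
            cfg$base_rate * cn$rate_scale, cfg
          )
        }
      }
    }
    if (supervised) {
      for (ci in sup_idx) {
        cn <- conns[[ci]]
        if (cn$reward_window == "late" && (t < late_start || t > late_end)) next
        nm <- names(conns)[ci]
        tr <- st$traces[[cn$source]][, 1]
        acc_src[[nm]] <- acc_src[[nm]] + tr
        post <- which(spk[[cn$target]][, 1] > 0)
        if (length(post)) {
          acc[[nm]][post, ] <- acc[[nm]][post, , drop = FALSE] +
            matrix(tr, length(post), length(tr), byrow = TRUE)
        }
      }
    }
    counts[["CLA-shape"]] <- counts[["CLA-shape"]] + spk[["CLA-shape"]][, 1]
    counts[["CLA-where"]] <- counts[["CLA-where"]] + spk[["CLA-where"]][, 1]
    counts[["Attention"]] <- counts[["Attention"]] + spk[["Attention"]][, 1]
    if (t >= late_start && t <= late_end) {
      counts[["CLA-where-late"]] <- counts[["CLA-where-late"]] + spk[["CLA-where"]][, 1]
    }

    # Sleep: per-layer renormalization at jittered intervals (the stated
    # interval is the mean; each inter-sleep gap is drawn from +/-50%).
    for (layer in names(net$renorm_interval)) {
      net$renorm_count[[layer]] <- net$renorm_count[[layer]] + 1L
      if (net$renorm_count[[layer]] >= net$renorm_next[[layer]]) {
        bn_renormalize_layer(net, layer)
        net$renorm_count[[layer]] <- 0L
        net$renorm_next[[layer]] <- max(
          1L, as.integer(net$renorm_interval[[layer]] * stats::runif(1, 0.5, 1.5))
        )
      }
    }
  }
  list(counts = counts, acc = acc, acc_src = acc_src)
}

# Apply a signed value-gated update to a supervised connection from the
# eligibility accumulated over a trial, restricted to the given target rows.
bn_apply_valuegated <- function(net, conn_name, acc, rows, rate, cfg) {
  if (!length(rows) || rate == 0) {
    return(invisible(net))
  }
  W <- net$conns[[conn_name]]$W
  W[rows, ] <- pmin(
    pmax(W[rows, , drop = FALSE] + rate * acc[rows, , drop = FALSE], cfg$weight_lower),
    cfg$weight_upper
  )
  net$conns[[conn_name]]$W <- W
  invisible(net)
}

#' Train a network on the single-object, noiseless protocol
#'
#' Runs the full concurrent learning protocol: on every presentation a
#' single letter moves across the retina along a random trajectory;
#' unsupervised burst-STDP shapes the shape and motion S2 layers online,
#' while supervised (value-gated) eligibility is accumulated and applied at
#' the end of the presentation according to the external supervisor's
#' judgment of the classifier pools (letter for CLA-shape, trajectory for
#' CLA-where) and of the attention module (updated only when the target
#' letter is present). Layers are renormalized at their sleep intervals and
#' the reward constants anneal across presentations.
#'
#' @param net A freshly built `bn_network` (modified in place and returned).
#' @param schedule A [training_schedule()].
#' @param cfg A [plasticity_config()].
#' @param rewards A [reward_schedule()]; its horizon defaults to the
#'   schedule's `anneal_horizon`.
#' @param unsupervised,supervised Enable/disable the two learning systems.
#' @param test_dynamics If `TRUE`, simulate with train-only groups
#'   disconnected (the supervised stage of the staged protocol, so the
#'   classifiers learn on the activity statistics they will see at test
#'   time).
#' @param progress_offset Presentations already performed (used internally
#'   for multi-epoch annealing).
#'
#' @return The network, with a `training_log` tibble field describing each
#'   presentation.
#' @export
train_network <- function(net, schedule = training_schedule(),
                          cfg = plasticity_config(),
                          rewards = reward_schedule(anneal_horizon = schedule$anneal_horizon),
                          unsupervised = TRUE, supervised = TRUE,
                          test_dynamics = FALSE, progress_offset = 0L) {
  stopifnot(inherits(net, "bn_network"))
  if (schedule$n_presentations == 0L) {
    return(invisible(net))
  }
  set.seed(schedule$seed)
  net$renorm_interval <- schedule$renorm_intervals
  if (is.null(net$renorm_count)) {
    net$renorm_count <- lapply(schedule$renorm_intervals, function(x) 0L)
  }
  if (is.null(net$renorm_next)) {
    net$renorm_next <- lapply(schedule$renorm_intervals, function(x) {
      max(1L, as.integer(x * stats::runif(1, 0.5, 1.5)))
    })
  }
  tt <- trajectory_table()
  log <- vector("list", schedule$epochs * schedule$n_presentations)
  pres_global <- progress_offset

  for (epoch in seq_len(schedule$epochs)) {
    for (pres in seq_len(schedule$n_presentations)) {
      letter <- sample(schedule$letters, 1)
      traj <- sample.int(8, 1)
      trial <- make_stimulus_trial(letter, traj,
        noise_p = schedule$train_noise, speed = net$speed
      )
      res <- bn_train_trial(net, trial, cfg,
        unsupervised = unsupervised, supervised = supervised,
        test_dynamics = test_dynamics
      )
      progress <- min(pres_global / rewards$anneal_horizon, 1)
      shape_j <- where_j <- list(winner = NA_character_, correct = NA, event = FALSE)
      if (supervised) {
        # A reward event judges the whole classifier: connections onto the
        # label pool's firing neurons are rewarded, connections onto firing
        # neurons of the competing pools are punished (annealed to zero).
        apply_pool_learning <- function(conn_name, pools, label, judgment) {
          if (!judgment$event) {
            return(invisible(NULL))
          }
          a <- res$acc[[conn_name]]
          fired_rows <- which(rowSums(a) > 0)
          pos <- intersect(pools[[label]], fired_rows)
          neg <- setdiff(fired_rows, pools[[label]])
          rate_pos <- value_gated_rate(cfg$base_rate, TRUE, progress, rewards)
          rate_neg <- value_gated_rate(cfg$base_rate, FALSE, progress, rewards)
          bn_apply_valuegated(net, conn_name, a, pos, rate_pos, cfg)
          bn_apply_valuegated(net, conn_name, a, neg, rate_neg, cfg)
          # Teacher drive: label-pool neurons that stayed silent are still
          # nudged toward the class's presynaptic signature (a silent pool
          # has no spike eligibility and could otherwise never recover).
          silent <- setdiff(pools[[label]], fired_rows)
          if (length(silent)) {
            a2 <- a
            a2[silent, ] <- matrix(0.25 * res$acc_src[[conn_name]],
              length(silent), ncol(a),
              byrow = TRUE
            )
            bn_apply_valuegated(net, conn_name, a2, silent, rate_pos, cfg)
          }
        }
        shape_j <- judge_response(
          res$counts[["CLA-shape"]], net$pools[["CLA-shape"]], letter
        )
        apply_pool_learning(
          "S2-shape-ex->CLA-shape", net$pools[["CLA-shape"]], letter, shape_j
        )
        where_j <- judge_response(
          res$counts[["CLA-where-late"]], net$pools[["CLA-where"]],
          paste0("traj", traj)
        )
        apply_pool_learning(
          "S2-where-ex->CLA-where", net$pools[["CLA-where"]],
          paste0("traj", traj), where_j
        )
        # Attention synapses are modified only when the target object is on
        # the retina; spiking attention neurons are treated as rewarded.
        if (letter == net$target_letter) {
          fired <- which(res$counts[["Attention"]] > 0)
          rate <- value_gated_rate(cfg$base_rate, TRUE, progress, rewards)
          bn_apply_valuegated(
            net, "S2-shape-ex->Attention",
            res$acc[["S2-shape-ex->Attention"]], fired, rate, cfg
          )
        }
      }
      pres_global <- pres_global + 1L
      log[[(epoch - 1L) * schedule$n_presentations + pres]] <- tibble::tibble(
        epoch = epoch, presentation = pres, letter = letter, traj = traj,
        shape_winner = shape_j$winner,
        shape_correct = shape_j$correct,
        where_winner = where_j$winner,
        where_correct = where_j$correct,
        progress = progress
      )
    }
  }
  net$training_log <- dplyr::bind_rows(
    if (!is.null(net$training_log)) net$training_log, log
  )
  net$presentations_done <- pres_global
  invisible(net)
}

#' Run only the unsupervised learning system
#'
#' Convenience wrapper over [train_network()] with supervised (value-gated)
#' learning disabled.
#'
#' @inheritParams train_network
#' @return The network, invisibly.
#' @export
train_unsupervised <- function(net, schedule = training_schedule(train_noise = 0.01),
                               cfg = plasticity_config()) {
  train_network(net, schedule, cfg, unsupervised = TRUE, supervised = FALSE)
}

#' Run only the value-gated (supervised) learning system
#'
#' Convenience wrapper over [train_network()] with unsupervised learning
#' disabled; intended for a staged protocol after [train_unsupervised()].
#'
#' @inheritParams train_network
#' @return The network, invisibly.
#' @export
train_value_gated <- function(net, schedule = training_schedule(),
                              cfg = plasticity_config(),
                              rewards = reward_schedule(anneal_horizon = schedule$anneal_horizon),
                              test_dynamics = TRUE) {
  train_network(net, schedule, cfg, rewards,
    unsupervised = FALSE, supervised = TRUE, test_dynamics = test_dynamics
  )
}

#' Consolidate only the unsupervised feature connections
#'
#' Renormalizes and binarizes the unsupervised plastic connections (the
#' shape and motion S2 feature layers), leaving the supervised classifier
#' connections real-valued. Used between the two stages of the staged
#' training protocol.
#'
#' @param net A `bn_network` after unsupervised training.
#' @param cfg A [plasticity_config()].
#' @return The network, invisibly.
#' @export
consolidate_unsupervised <- function(net, cfg = plasticity_config()) {
  unsup_layers <- unique(vapply(
    Filter(function(cn) cn$plastic && !cn$supervised, net$conns),
    function(cn) cn$target, character(1)
  ))
  for (layer in unsup_layers) bn_renormalize_layer(net, layer)
  for (ci in seq_along(net$conns)) {
    cn <- net$conns[[ci]]
    if (cn$plastic && !cn$supervised) {
      th <- if (is.na(cn$bin_threshold)) cfg$binarize_threshold else cn$bin_threshold
      net$conns[[ci]]$W <- binarize_weights(cn$W, th)
    }
  }
  invisible(net)
}

#' Consolidate a trained network for testing
#'
#' Performs a final renormalization of every plastic layer, snaps all
#' plastic weights to binary values, and attaches a hardware-compatibility
#' report. Consolidation is idempotent.
#'
#' @param net A trained `bn_network`.
#' @param cfg A [plasticity_config()] (supplies the binarization
#'   threshold).
#' @return The network, with `binarized = TRUE` and a `hardware_report`
#'   field.
#' @export
consolidate <- function(net, cfg = plasticity_config()) {
  for (layer in names(net$plastic_in)) {
    bn_renormalize_layer(net, layer)
  }
  for (ci in seq_along(net$conns)) {
    cn <- net$conns[[ci]]
    if (cn$plastic) {
      th <- if (is.na(cn$bin_threshold)) cfg$binarize_threshold else cn$bin_threshold
      net$conns[[ci]]$W <- binarize_weights(cn$W, th)
    }
  }
  net$binarized <- TRUE
  net$hardware_report <- validate_hardware(net)
  invisible(net)
}

#' Build, train and consolidate the standard network
#'
#' One-call pipeline producing the consolidated network used by the
#' evaluation experiments.
#'
#' @param seed Integer seed (weights and training stream).
#' @param epochs Training epochs (1 for the shape-recognition experiment;
#'   the noise-robustness experiments may use more).
#' @param n_presentations Unsupervised-stage presentations per epoch (run
#'   with a small exploration noise).
#' @param n_supervised Value-gated-stage presentations per epoch (run
#'   noiseless under test dynamics; the reward constants anneal over this
#'   stage).
#' @param cfg A [plasticity_config()].
#' @return A consolidated `bn_network`.
#' @export
train_standard_network <- function(seed = 1L, epochs = 1L,
                                   n_presentations = 400L,
                                   n_supervised = 900L,
                                   cfg = plasticity_config()) {
  net <- build_network(seed = seed)
  sched1 <- training_schedule(
    n_presentations = n_presentations, epochs = epochs,
    train_noise = 0.01, seed = seed + 1L
  )
  train_unsupervised(net, sched1, cfg)
  consolidate_unsupervised(net, cfg)
  sched2 <- training_schedule(
    n_presentations = n_supervised, epochs = epochs,
    anneal_horizon = n_supervised, seed = seed + 2L
  )
  train_value_gated(net, sched2, cfg)
  consolidate(net, cfg)
  net
}
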