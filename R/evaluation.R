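# Evaluation: batched test-mode simulation of trial streams, trial-outcome
# classification (Correct / Incorrect / NoDecision by the last motor
# response), and the experiment sweeps: shape recognition, motion-direction
# noise sweep, single-object and two-object full-task sweeps, and the
# attention ablation.

# Run a batch of same-duration trials in test mode (train-only groups
# disconnected, binarized weights). Returns per-trial final motor index
# (NA if silent), decision tick, and total spike counts of the groups named
# in `record`.
bn_run_batch <- function(net, trials, record = character()) {
  stopifnot(length(trials) >= 1)
  B <- length(trials)
  dur <- trials[[1]]$duration
  stopifnot(all(vapply(trials, function(tr) tr$duration, numeric(1)) == dur))
  npx <- net$groups[[net$retina]]$n

  base <- lapply(trials, bn_trial_frames) # each npx x dur
  noise_p <- vapply(trials, function(tr) tr$noise_p, numeric(1))
  p_mat <- matrix(noise_p, npx, B, byrow = TRUE)

  st <- bn_init_state(net, B)
  last_motor <- rep(NA_integer_, B)
  last_tick <- rep(NA_integer_, B)
  counts <- lapply(record, function(gn) matrix(0, net$groups[[gn]]$n, B))
  names(counts) <- record

  frame_t <- matrix(0L, npx, B)
  for (t in seq_len(dur)) {
    for (b in seq_len(B)) frame_t[, b] <- base[[b]][, t]
    if (any(noise_p > 0)) {
      flips <- matrix(stats::runif(npx * B), npx, B) < p_mat
      frame_t[flips] <- 1L - frame_t[flips]
    }
    spk <- bn_tick(net, st, frame_t, testing = TRUE)
    mot <- spk[["Motor"]]
    fired_cols <- which(colSums(mot) > 0)
    for (b in fired_cols) {
      last_motor[b] <- which(mot[, b] > 0)[1]
      last_tick[b] <- t
    }
    for (gn in record) counts[[gn]] <- counts[[gn]] + spk[[gn]]
  }
  list(last_motor = last_motor, last_tick = last_tick, counts = counts)
}

#' Classify the outcome of a trial from its motor log
#'
#' The last motor spike before the object leaves the retina is the
#' network's final decision; no motor spike at all is a "NoDecision". Under
#' the `"object"` convention the decision is Correct when it matches the
#' expected catcher placement ([expected_response()]); a distractor-only
#' trial is Correct exactly when no response occurred. Under the
#' `"motion"` convention the decision is Correct when it matches the
#' placement implied by the true trajectory for the presented letter (i.e.
#' the motor output identifies the direction of motion).
#'
#' @param final_motor Integer motor index of the last motor spike, or `NA`
#'   if none was recorded.
#' @param trial The `bn_trial` that was presented.
#' @param convention `"object"` (catch/avoid task) or `"motion"`
#'   (direction-detection task).
#' @param decision_tick Optional tick of the final motor spike.
#'
#' @return A one-row tibble: `outcome` (`"Correct"`, `"Incorrect"`,
#'   `"NoDecision"`), `final_motor`, `decision_tick`, `expected`.
#' @export
classify_outcome <- function(final_motor, trial,
                             convention = c("object", "motion"),
                             decision_tick = NA_integer_) {
  convention <- match.arg(convention)
  expected <- expected_response(trial)
  if (convention == "motion" && is.na(expected)) {
    # Distractor letters are routed through the avoidance pathway, so the
    # placement opposite the trajectory identifies the direction of motion.
    tt <- trajectory_table()
    expected <- tt$opposite[tt$traj == trial$trajs[1]]
  }
  outcome <- if (is.na(final_motor)) {
    if (convention == "object" && is.na(expected)) "Correct" else "NoDecision"
  } else if (!is.na(expected) && final_motor == expected) {
    "Correct"
  } else {
    "Incorrect"
  }
  tibble::tibble(
    outcome = outcome, final_motor = final_motor,
    decision_tick = decision_tick, expected = expected
  )
}

# Generate the trial list for one noise level of a task.
bn_task_trials <- function(task, n, noise_p, speed) {
  purrr::map(seq_len(n), function(i) {
    switch(task,
      motion_only = make_trial("single",
        noise_p = noise_p,
        letters = c("T", "L", "J"), speed = speed
      ),
      single_object = make_trial("single",
        noise_p = noise_p,
        letters = c("T", "L"), speed = speed
      ),
      two_object = make_trial("two_object", noise_p = noise_p, speed = speed)
    )
  })
}

#' Noise-robustness sweep
#'
#' Runs `n_per_level` trials at each pixel-flip noise level through the
#' consolidated network and classifies each trial by the last-motor-response
#' rule. The `motion_only` task draws all three letters and scores direction
#' correctness; `single_object` draws T and L equiprobably and scores
#' catcher correctness; `two_object` uses the 25/25/50 T/L/both mix
#' ("catch the T if present, else avoid the L").
#'
#' @param net A consolidated `bn_network`.
#' @param task One of `"motion_only"`, `"single_object"`, `"two_object"`.
#' @param levels Numeric vector of noise probabilities.
#' @param n_per_level Trials per level (default 100).
#' @param seed Integer seed for the trial streams (one sub-stream per
#'   level, so arms with the same seed see identical trials).
#'
#' @return A tibble of class `bn_sweep`: one row per level with counts and
#'   fractions of Correct / Incorrect / NoDecision outcomes.
#' @export
noise_sweep <- function(net, task = c("motion_only", "single_object", "two_object"),
                        levels = seq(0, 0.25, by = 0.01), n_per_level = 100L,
                        seed = 1L) {
  task <- match.arg(task)
  convention <- if (task == "motion_only") "motion" else "object"
  rows <- purrr::map(seq_along(levels), function(li) {
    set.seed(seed + 1000L * li)
    trials <- bn_task_trials(task, n_per_level, levels[li], net$speed)
    res <- bn_run_batch(net, trials)
    outs <- purrr::map_chr(seq_along(trials), function(b) {
      classify_outcome(res$last_motor[b], trials[[b]], convention)$outcome
    })
    tibble::tibble(
      task = task, noise = levels[li], n = n_per_level,
      correct = sum(outs == "Correct"),
      incorrect = sum(outs == "Incorrect"),
      no_decision = sum(outs == "NoDecision")
    )
  })
  out <- dplyr::bind_rows(rows)
  out$frac_correct <- out$correct / out$n
  out$frac_incorrect <- out$incorrect / out$n
  out$frac_no_decision <- out$no_decision / out$n
  class(out) <- c("bn_sweep", class(out))
  out
}

#' Shape-recognition experiment
#'
#' Trains one network per seed for a single epoch, then tests each on
#' noiseless presentations of every letter (random start corner and
#' direction) and scores a presentation correct when the winning CLA-shape
#' pool (largest summed spike count over the trial) matches the presented
#' letter. Accuracies are averaged across the seeds.
#'
#' @param seeds Integer vector of random initializations (default 4 seeds).
#' @param n_per_letter Test presentations per letter per network
#'   (default 100).
#' @param epochs Training epochs per network (default 1).
#' @param n_presentations Training presentations per epoch.
#'
#' @return A tibble with one row per letter: mean accuracy and standard
#'   error over seeds, plus the per-seed accuracies nested in `by_seed`.
#' @export
shape_recognition_experiment <- function(seeds = 1:4, n_per_letter = 100L,
                                         epochs = 1L, n_presentations = 400L) {
  per_seed <- purrr::map(seeds, function(sd) {
    net <- train_standard_network(
      seed = sd, epochs = epochs,
      n_presentations = n_presentations
    )
    set.seed(sd + 5000L)
    purrr::map_dfr(c("T", "L", "J"), function(letter) {
      trials <- purrr::map(seq_len(n_per_letter), function(i) {
        make_stimulus_trial(letter, sample.int(8, 1),
          noise_p = 0,
          speed = net$speed
        )
      })
      res <- bn_run_batch(net, trials, record = "CLA-shape")
      hits <- vapply(seq_along(trials), function(b) {
        j <- judge_response(
          res$counts[["CLA-shape"]][, b], net$pools[["CLA-shape"]], letter
        )
        isTRUE(j$correct)
      }, logical(1))
      tibble::tibble(seed = sd, letter = letter, accuracy = mean(hits))
    })
  })
  all <- dplyr::bind_rows(per_seed)
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$letter),
    mean_accuracy = mean(.data$accuracy),
    se = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  out$by_seed <- purrr::map(out$letter, function(l) all[all$letter == l, ])
  out
}

#' Attention-ablation experiment
#'
#' Runs the two-object noise sweep on the intact network and on a copy with
#' all attention outputs severed, using identical trial streams (paired
#' seeds), and returns both arms in one table.
#'
#' @param net A consolidated `bn_network` trained with the attention module.
#' @param levels Noise levels (default 0 to 12%).
#' @param n_per_level Trials per level.
#' @param seed Integer seed shared by both arms.
#'
#' @return A `bn_sweep` tibble with an extra `arm` column
#'   (`"intact"` / `"severed"`).
#' @export
attention_ablation_experiment <- function(net, levels = seq(0, 0.12, by = 0.02),
                                          n_per_level = 100L, seed = 1L) {
  intact <- noise_sweep(net, "two_object", levels, n_per_level, seed)
  lesioned <- sever_attention(net)
  severed <- noise_sweep(lesioned, "two_object", levels, n_per_level, seed)
  intact$arm <- "intact"
  severed$arm <- "severed"
  out <- dplyr::bind_rows(intact, severed)
  class(out) <- c("bn_sweep", class(out))
  out
}
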