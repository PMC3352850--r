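# Synthetic visual world: letter glyphs moving across a 10x10 binary retina
# along 8 corner/direction trajectories, with independent per-pixel flip
# noise redrawn every tick.

RETINA_SIZE <- 10L
GLYPH_SIZE <- 4L

#' Letter glyph bitmaps
#'
#' Returns the binary bitmap of one of the three letter stimuli. Glyphs are
#' 4x4 with 2-pixel-thick strokes (12 on-pixels each) so that every letter,
#' at every position along its trajectory, drives at least one motion-stream
#' receptive-field window above its presence threshold:
#' * `T` -- top bar plus centre stem (target object),
#' * `L` -- left stem plus bottom-right block (avoidance object),
#' * `J` -- right stem plus bottom-left block (distractor; mirror of L).
#'
#' @param letter One of `"T"`, `"L"`, `"J"`.
#' @return A 4x4 0/1 integer matrix.
#' @export
#' @examples
#' glyph_bitmap("T")
glyph_bitmap <- function(letter = c("T", "L", "J")) {
  letter <- match.arg(letter)
  g <- matrix(0L, GLYPH_SIZE, GLYPH_SIZE)
  switch(letter,
    T = {
      g[1:2, ] <- 1L
      g[3:4, 2:3] <- 1L
    },
    L = {
      g[, 1:2] <- 1L
      g[3:4, 3:4] <- 1L
    },
    J = {
      g[, 3:4] <- 1L
      g[3:4, 1:2] <- 1L
    }
  )
  g
}

#' The eight corner/direction trajectories
#'
#' An object appears fully visible in one of the four corners of the retina
#' and moves one pixel every `speed` ticks, laterally (along the top or
#' bottom edge) or vertically (along the left or right edge), until it has
#' moved completely out of the field. Each trajectory is also the identity of
#' a catcher placement: the motor neuron with the same id places the catcher
#' at the trajectory's arrival corner, facing the incoming object.
#'
#' @return A tibble with one row per trajectory: `traj` (id 1--8), `corner`
#'   (`"UL"`, `"UR"`, `"LL"`, `"LR"`), `direction` (`"lateral"` or
#'   `"vertical"`), `row0`, `col0` (0-based anchor of the glyph's top-left
#'   cell at onset), `drow`, `dcol` (per-step displacement), and `opposite`
#'   (the trajectory id of the diagonally opposite placement, used for
#'   avoidance responses).
#' @export
trajectory_table <- function() {
  if (!is.null(.bn_cache$traj)) {
    return(.bn_cache$traj)
  }
  corners <- c("UL", "UR", "LL", "LR")
  far <- RETINA_SIZE - GLYPH_SIZE # 0-based anchor of the far corner
  anchor <- list(
    UL = c(0L, 0L), UR = c(0L, far), LL = c(far, 0L), LR = c(far, far)
  )
  tb <- tibble::tibble(
    traj = 1:8,
    corner = rep(corners, 2),
    direction = rep(c("lateral", "vertical"), each = 4)
  )
  tb$row0 <- vapply(tb$corner, function(cr) anchor[[cr]][1], integer(1))
  tb$col0 <- vapply(tb$corner, function(cr) anchor[[cr]][2], integer(1))
  tb$drow <- ifelse(tb$direction == "vertical", ifelse(tb$row0 == 0L, 1L, -1L), 0L)
  tb$dcol <- ifelse(tb$direction == "lateral", ifelse(tb$col0 == 0L, 1L, -1L), 0L)
  diag_corner <- c(UL = "LR", UR = "LL", LL = "UR", LR = "UL")
  tb$opposite <- vapply(seq_len(8), function(i) {
    tb$traj[tb$corner == diag_corner[[tb$corner[i]]] &
      tb$direction == tb$direction[i]]
  }, integer(1))
  .bn_cache$traj <- tb
  tb
}

.bn_cache <- new.env(parent = emptyenv())

#' Number of simulation ticks in one stimulus presentation
#'
#' The retina is square, so the dwell time is the same for every trajectory:
#' the glyph anchor visits `RETINA_SIZE` positions at `speed` ticks each.
#'
#' @param speed Ticks per one-pixel movement step (default 10).
#' @return Integer tick count.
#' @export
trial_duration <- function(speed = 10L) {
  as.integer(RETINA_SIZE * speed)
}

#' Construct a stimulus trial
#'
#' @param letters Character vector of 1 or 2 letters from `"T"`, `"L"`,
#'   `"J"`.
#' @param trajs Integer vector (same length) of trajectory ids, see
#'   [trajectory_table()].
#' @param noise_p Per-pixel flip probability in `[0, 1]`, redrawn
#'   independently every tick.
#' @param speed Ticks per movement step (default 10).
#'
#' @return An object of class `bn_trial`.
#' @export
make_stimulus_trial <- function(letters, trajs, noise_p = 0, speed = 10L) {
  stopifnot(
    length(letters) %in% 1:2, length(trajs) == length(letters),
    all(letters %in% c("T", "L", "J")), all(trajs %in% 1:8),
    noise_p >= 0, noise_p <= 1
  )
  structure(
    list(
      letters = letters, trajs = as.integer(trajs),
      noise_p = noise_p, speed = as.integer(speed),
      duration = trial_duration(speed)
    ),
    class = "bn_trial"
  )
}

#' Render the noiseless retina frame of a trial at a given tick
#'
#' Each object is drawn at its trajectory position (the anchor advances one
#' pixel every `speed` ticks); pixels outside the retina are clipped and
#' overlapping objects are combined with logical OR. After the trial
#' duration the frame is blank (all objects have exited).
#'
#' @param trial A [make_stimulus_trial()] object.
#' @param t Tick, `>= 0` (tick 0 is onset).
#' @return A 10x10 0/1 matrix.
#' @export
render_frame <- function(trial, t) {
  stopifnot(t >= 0)
  tt <- trajectory_table()
  frame <- matrix(0L, RETINA_SIZE, RETINA_SIZE)
  step <- t %/% trial$speed
  for (i in seq_along(trial$letters)) {
    tr <- tt[tt$traj == trial$trajs[i], ]
    r0 <- tr$row0 + tr$drow * step # 0-based anchor
    c0 <- tr$col0 + tr$dcol * step
    g <- glyph_bitmap(trial$letters[i])
    for (gr in seq_len(GLYPH_SIZE)) {
      rr <- r0 + gr # 1-based retina row
      if (rr < 1 || rr > RETINA_SIZE) next
      for (gc in seq_len(GLYPH_SIZE)) {
        cc <- c0 + gc
        if (cc < 1 || cc > RETINA_SIZE) next
        if (g[gr, gc] == 1L) frame[rr, cc] <- 1L
      }
    }
  }
  frame
}

#' Flip retina pixels independently with probability `p`
#'
#' @param frame A 0/1 matrix.
#' @param p Flip probability per pixel.
#' @return A 0/1 matrix of the same shape.
#' @export
inject_noise <- function(frame, p) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0) {
    return(frame)
  }
  flips <- matrix(stats::runif(length(frame)) < p, nrow(frame), ncol(frame))
  out <- frame
  out[flips] <- 1L - out[flips]
  out
}

#' Draw a random stimulus trial from an object mix
#'
#' Letters, corners and directions are drawn independently and uniformly
#' where the mix does not fix them. The default two-object mix is 25%
#' target only (T), 25% avoidance only (L), 50% both.
#'
#' @param object_mix Either `"single"` (one letter drawn uniformly from
#'   `letters`) or `"two_object"` (T-only / L-only / both with
#'   probabilities `mix_probs`).
#' @param noise_p Per-pixel flip probability.
#' @param letters Letter pool for the single-object mix (default all
#'   three).
#' @param mix_probs Probabilities of (T only, L only, both) for the
#'   two-object mix.
#' @param speed Ticks per movement step.
#'
#' @return A `bn_trial`.
#' @export
make_trial <- function(object_mix = c("single", "two_object"), noise_p = 0,
                       letters = c("T", "L", "J"),
                       mix_probs = c(0.25, 0.25, 0.5), speed = 10L) {
  object_mix <- match.arg(object_mix)
  if (object_mix == "single") {
    lets <- sample(letters, 1)
    trajs <- sample.int(8, 1)
  } else {
    stopifnot(abs(sum(mix_probs) - 1) < 1e-9)
    kind <- sample(c("T", "L", "both"), 1, prob = mix_probs)
    lets <- switch(kind, T = "T", L = "L", both = c("T", "L"))
    trajs <- sample.int(8, length(lets), replace = TRUE)
  }
  make_stimulus_trial(lets, trajs, noise_p = noise_p, speed = speed)
}

#' Expected catcher placement for a trial
#'
#' The catcher must be placed in front of an arriving target (T): the motor
#' index equals the T's trajectory id. If no T is present but an avoidance
#' object (L) is, the catcher goes to the opposite placement: the trajectory
#' diagonally opposite the L's. A distractor-only (J) trial should elicit no
#' motor response.
#'
#' @param trial A `bn_trial`.
#' @return Integer motor index 1--8, or `NA_integer_` for J-only trials.
#' @export
expected_response <- function(trial) {
  tt <- trajectory_table()
  if ("T" %in% trial$letters) {
    return(trial$trajs[match("T", trial$letters)])
  }
  if ("L" %in% trial$letters) {
    tr <- trial$trajs[match("L", trial$letters)]
    return(tt$opposite[tt$traj == tr])
  }
  NA_integer_
}

# Precompute the noiseless retina frames of a trial as a n_pixels x duration
# matrix (column-major pixel order, one column per tick).
bn_trial_frames <- function(trial) {
  steps <- trial$duration %/% trial$speed
  cols <- matrix(0L, RETINA_SIZE * RETINA_SIZE, trial$duration)
  for (s in seq_len(steps) - 1L) {
    f <- as.integer(render_frame(trial, s * trial$speed))
    for (k in seq_len(trial$speed)) {
      cols[, s * trial$speed + k] <- f
    }
  }
  cols
}
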