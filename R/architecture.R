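# The full visual-system architecture: 23 neuron groups across retina,
# shape, motion, attention and decision modules, with topographic hard-wired
# circuits, random-initialized plastic connections, winner-take-all
# inhibition, top-down attention feedback and the motor decision wiring.

#' Default neuron-group table of the shipped architecture
#'
#' One row per neuron group: module, grid shape, LIF parameters, axon type
#' and whether the group is active only during training. The retina row is
#' an input clamp and carries no LIF parameters (`NA`).
#'
#' @return A tibble with columns `name`, `module`, `type`, `rows`, `cols`,
#'   `train_only`, `threshold`, `leak`, `s_plus`, `s_minus`.
#' @export
default_architecture <- function() {
  tibble::tribble(
    ~name, ~module, ~type, ~rows, ~cols, ~train_only, ~threshold, ~leak, ~s_plus, ~s_minus,
    "Retina", "retina", "exc", 10L, 10L, FALSE, NA, NA, NA, NA,
    "S1-ver", "shape", "exc", 10L, 5L, FALSE, 31, 16, 16, 0,
    "S1-hor", "shape", "exc", 5L, 10L, FALSE, 31, 16, 16, 0,
    "C1-ver-ex", "shape", "exc", 10L, 5L, FALSE, 4, 2, 8, 64,
    "C1-hor-ex", "shape", "exc", 5L, 10L, FALSE, 4, 2, 8, 64,
    "C1-ver-inh", "shape", "inh", 10L, 5L, FALSE, 4, 2, 32, 0,
    "C1-hor-inh", "shape", "inh", 5L, 10L, FALSE, 4, 2, 32, 0,
    "C1-ver-max", "shape", "exc", 5L, 5L, FALSE, 1, 2, 32, 0,
    "C1-hor-max", "shape", "exc", 5L, 5L, FALSE, 16, 2, 32, 0,
    "S2-shape-ex", "shape", "exc", 6L, 6L, FALSE, 100, 64, 32, 255,
    "S2-shape-inh", "shape", "inh", 6L, 6L, TRUE, 2, 2, 32, 0,
    "CLA-shape", "shape", "exc", 3L, 10L, FALSE, 16, 2, 32, 128,
    "S1-inst", "motion", "exc", 4L, 4L, FALSE, 27, 26, 4, 0,
    "S1-del", "motion", "exc", 4L, 4L, FALSE, 27, 26, 4, 0,
    "S2-where-ex", "motion", "exc", 4L, 6L, FALSE, 100, 64, 64, 192,
    "S2-where-inh", "motion", "inh", 4L, 6L, TRUE, 16, 2, 32, 0,
    "CLA-where", "motion", "exc", 8L, 10L, FALSE, 32, 16, 64, 0,
    "Attention", "attention", "inh", 4L, 6L, FALSE, 5, 16, 16, 128,
    "Target", "decision", "exc", 1L, 8L, FALSE, 21, 2, 1, 80,
    "Obstacle", "decision", "exc", 1L, 8L, FALSE, 21, 2, 1, 80,
    "Shape-inh", "decision", "inh", 1L, 3L, FALSE, 4, 4, 1, 0,
    "Shape-decision", "decision", "exc", 1L, 3L, FALSE, 13, 3, 1, 0,
    "Motor", "decision", "exc", 1L, 8L, FALSE, 8, 7, 16, 0
  )
}

#' Topographic (windowed) binary wiring between two grids
#'
#' Connects each destination neuron to exactly the source cells inside its
#' receptive-field window; windows of size `rf` are placed at `stride`
#' offsets and must tile the source grid into exactly the destination grid.
#' Grids are indexed column-major (R order). `rf = c(1, 1)`,
#' `stride = c(1, 1)` with equal grids gives identity wiring.
#'
#' @param src_grid,dst_grid Integer `c(rows, cols)` of the two grids.
#' @param rf Receptive-field window size `c(rows, cols)`.
#' @param stride Window offset step `c(rows, cols)`.
#' @return A binary weight matrix with `prod(dst_grid)` rows and
#'   `prod(src_grid)` columns.
#' @export
#' @examples
#' dim(wire_topographic(c(10, 10), c(4, 4), rf = c(4, 4), stride = c(2, 2)))
wire_topographic <- function(src_grid, dst_grid, rf, stride = c(1L, 1L)) {
  n_wind <- (src_grid - rf) %/% stride + 1L
  if (any((src_grid - rf) %% stride != 0L) || !all(n_wind == dst_grid)) {
    stop(
      "rf ", paste(rf, collapse = "x"), " with stride ",
      paste(stride, collapse = "x"), " tiles a ",
      paste(src_grid, collapse = "x"), " grid into ",
      paste(n_wind, collapse = "x"), " windows, not ",
      paste(dst_grid, collapse = "x"),
      call. = FALSE
    )
  }
  W <- matrix(0, prod(dst_grid), prod(src_grid))
  for (dc in seq_len(dst_grid[2])) {
    for (dr in seq_len(dst_grid[1])) {
      d_idx <- (dc - 1L) * dst_grid[1] + dr
      rows <- (dr - 1L) * stride[1] + seq_len(rf[1])
      cols <- (dc - 1L) * stride[2] + seq_len(rf[2])
      for (sc in cols) {
        W[d_idx, (sc - 1L) * src_grid[1] + rows] <- 1
      }
    }
  }
  W
}

#' Dense random plastic wiring
#'
#' Initializes a plastic connection with weights drawn i.i.d. uniformly in
#' `[0, 1)`; reproducible under the caller's RNG seed.
#'
#' @param n_src,n_dst Source and destination group sizes.
#' @return An `n_dst x n_src` weight matrix.
#' @export
wire_random <- function(n_src, n_dst) {
  matrix(stats::runif(n_src * n_dst), n_dst, n_src)
}

# Binary wiring from every source neuron to every target except the one at
# the same index (reciprocal "inhibit everyone else" circuits).
wire_all_but_self <- function(n) {
  W <- matrix(1, n, n)
  diag(W) <- 0
  W
}

# Localized neighbourhood wiring on a grid: source cell (r, c) connects to
# target cells within Chebyshev distance `radius`, excluding the cell at its
# own position.
wire_neighbourhood <- function(grid, radius = 1L) {
  n <- prod(grid)
  W <- matrix(0, n, n)
  rows <- rep(seq_len(grid[1]), grid[2])
  cols <- rep(seq_len(grid[2]), each = grid[1])
  for (s in seq_len(n)) {
    near <- abs(rows - rows[s]) <= radius & abs(cols - cols[s]) <= radius
    near[s] <- FALSE
    W[near, s] <- 1
  }
  W
}

# Pool wiring: target neuron k reads all neurons of pool k of the source
# layer (pools = grid rows, column-major indexing).
wire_pools <- function(pools, n_src, n_dst) {
  stopifnot(length(pools) == n_dst)
  W <- matrix(0, n_dst, n_src)
  for (k in seq_len(n_dst)) W[k, pools[[k]]] <- 1
  W
}

# Row-pool index list of an r x c grid in column-major order.
grid_row_pools <- function(rows, cols) {
  lapply(seq_len(rows), function(r) seq(r, rows * cols, by = rows))
}

#' Build the spiking network
#'
#' Instantiates all neuron groups of the architecture table, hard-wires the
#' topographic circuits (edge detectors, max pooling, winner-take-all
#' inhibition, attention feedback, decision wiring) and initializes every
#' plastic connection with uniform random weights in `[0, 1)`.
#'
#' @param arch Group table as produced by [default_architecture()].
#' @param seed Optional integer seed for the random plastic weights.
#' @param speed Ticks per one-pixel stimulus movement step; the motion
#'   stream's delay line defaults to the same value.
#' @param delay Delay (ticks) of the retina to S1-del connection.
#' @param c1_inh_radius Radius of the localized C1 inhibitory feedback
#'   neighbourhood (default 1, i.e. 3x3 minus centre).
#' @param target_letter The letter the attention module is trained to
#'   prefer; attention's hard-wired inhibition spares the matching
#'   CLA-shape pool (default `"T"`).
#'
#' @return An object of class `bn_network` (an environment holding groups,
#'   connections, pools and simulation state).
#' @export
#' @examples
#' net <- build_network(seed = 1)
#' length(net$groups) # 23
build_network <- function(arch = default_architecture(), seed = NULL,
                          speed = 10L, delay = speed,
                          c1_inh_radius = 1L, target_letter = "T") {
  if (!is.null(seed)) set.seed(seed)
  net <- new.env(parent = emptyenv())
  class(net) <- "bn_network"
  net$retina <- "Retina"
  net$letters <- c("T", "L", "J")
  net$target_letter <- target_letter
  net$speed <- as.integer(speed)
  # Reward window for trajectory judging: the last few movement steps, when
  # the object is at its arrival segment (see the methods vignette).
  net$late_dwells <- 4L
  net$binarized <- FALSE

  net$groups <- purrr::pmap(arch, function(name, module, type, rows, cols,
                                           train_only, threshold, leak,
                                           s_plus, s_minus) {
    list(
      name = name, module = module,
      axon_type = if (type == "inh") "inhibitory" else "excitatory",
      grid = c(rows, cols), n = rows * cols, train_only = train_only,
      threshold = ifelse(is.na(threshold), 1, threshold),
      leak = ifelse(is.na(leak), 0, leak),
      s_plus = ifelse(is.na(s_plus), 0, s_plus),
      s_minus = ifelse(is.na(s_minus), 0, s_minus),
      is_input = name == "Retina",
      has_trace = FALSE
    )
  })
  names(net$groups) <- arch$name
  grids <- lapply(net$groups, function(g) g$grid)
  sizes <- lapply(net$groups, function(g) g$n)

  # Pools: CLA-shape rows = letters (T, L, J); CLA-where rows = trajectories.
  net$pools <- list(
    `CLA-shape` = stats::setNames(grid_row_pools(3L, 10L), net$letters),
    `CLA-where` = stats::setNames(grid_row_pools(8L, 10L), paste0("traj", 1:8))
  )

  tt <- trajectory_table()
  opp <- tt$opposite
  motor_catch <- diag(8) # Target k -> Motor k
  motor_avoid <- matrix(0, 8, 8) # Obstacle k -> Motor opposite(k)
  for (k in 1:8) motor_avoid[opp[k], k] <- 1

  # Shape-inh routing: the pool classifying the target letter silences the
  # avoidance pathway; avoidance and distractor pools silence the catch
  # pathway (see the decision-module discussion in the methods vignette).
  letter_is_target <- net$letters == target_letter
  shapeinh_to_target <- matrix(0, 8, 3)
  shapeinh_to_obstacle <- matrix(0, 8, 3)
  shapeinh_to_target[, !letter_is_target] <- 1
  shapeinh_to_obstacle[, letter_is_target] <- 1

  # Attention spares the CLA-shape pool of the target letter.
  att_to_clashape <- matrix(0, 30, 24)
  spare <- net$pools$`CLA-shape`[[target_letter]]
  att_to_clashape[setdiff(1:30, spare), ] <- 1

  topo <- function(src, dst, rf, stride) {
    wire_topographic(grids[[src]], grids[[dst]], rf, stride)
  }
  rnd <- function(src, dst) wire_random(sizes[[src]], sizes[[dst]])

  # rate_scale: per-connection multiplier on the base learning rate,
  # calibrated per stream so that a winning neuron's in-use weights reach
  # the upper weight bound roughly once per sleep interval (the regime in
  # which renormalization prunes stale weights; see the methods vignette).
  # bin_threshold: per-connection binarization threshold (NA = use the
  # global plasticity-config default). The motion feature connections use a
  # lower threshold so that consolidated cells keep their full edge-segment
  # window group (sustained, noise-robust n-of-m detectors) rather than
  # only the 3-4 strongest windows.
  conn <- function(source, target, W, sign = NULL, plastic = FALSE,
                   supervised = FALSE, delay = 0L, reward_window = "full",
                   rate_scale = 1, bin_threshold = NA_real_) {
    if (is.null(sign)) sign <- net$groups[[source]]$axon_type
    list(
      source = source, target = target, W = W, sign = sign,
      plastic = plastic, supervised = supervised, delay = as.integer(delay),
      reward_window = reward_window, rate_scale = rate_scale,
      bin_threshold = bin_threshold
    )
  }

  cl <- list(
    conn("Retina", "S1-ver", topo("Retina", "S1-ver", c(1L, 2L), c(1L, 2L))),
    conn("Retina", "S1-hor", topo("Retina", "S1-hor", c(2L, 1L), c(2L, 1L))),
    conn("Retina", "S1-inst", topo("Retina", "S1-inst", c(4L, 4L), c(2L, 2L))),
    conn("Retina", "S1-del", topo("Retina", "S1-del", c(4L, 4L), c(2L, 2L)),
      delay = delay
    ),
    conn("S1-ver", "C1-ver-ex", topo("S1-ver", "C1-ver-ex", c(1L, 1L), c(1L, 1L))),
    conn("S1-hor", "C1-hor-ex", topo("S1-hor", "C1-hor-ex", c(1L, 1L), c(1L, 1L))),
    conn("C1-ver-ex", "C1-ver-inh", topo("C1-ver-ex", "C1-ver-inh", c(1L, 1L), c(1L, 1L))),
    conn("C1-hor-ex", "C1-hor-inh", topo("C1-hor-ex", "C1-hor-inh", c(1L, 1L), c(1L, 1L))),
    conn("C1-ver-inh", "C1-ver-ex", wire_neighbourhood(grids[["C1-ver-ex"]], c1_inh_radius),
      delay = 1L
    ),
    conn("C1-hor-inh", "C1-hor-ex", wire_neighbourhood(grids[["C1-hor-ex"]], c1_inh_radius),
      delay = 1L
    ),
    conn("C1-ver-ex", "C1-ver-max", topo("C1-ver-ex", "C1-ver-max", c(2L, 1L), c(2L, 1L))),
    conn("C1-hor-ex", "C1-hor-max", topo("C1-hor-ex", "C1-hor-max", c(1L, 2L), c(1L, 2L))),
    conn("C1-ver-max", "S2-shape-ex", rnd("C1-ver-max", "S2-shape-ex"),
      plastic = TRUE, rate_scale = 0.1, bin_threshold = 0.65
    ),
    conn("C1-hor-max", "S2-shape-ex", rnd("C1-hor-max", "S2-shape-ex"),
      plastic = TRUE, rate_scale = 0.1, bin_threshold = 0.65
    ),
    conn("S2-shape-ex", "S2-shape-inh", topo("S2-shape-ex", "S2-shape-inh", c(1L, 1L), c(1L, 1L))),
    conn("S2-shape-inh", "S2-shape-ex", wire_all_but_self(36L)),
    conn("S2-shape-ex", "CLA-shape", rnd("S2-shape-ex", "CLA-shape"),
      plastic = TRUE, supervised = TRUE, rate_scale = 4, bin_threshold = 0.6
    ),
    conn("S2-shape-ex", "Attention", rnd("S2-shape-ex", "Attention"),
      plastic = TRUE, supervised = TRUE, rate_scale = 4, bin_threshold = 0.7
    ),
    conn("S1-inst", "S2-where-ex", rnd("S1-inst", "S2-where-ex"),
      plastic = TRUE, bin_threshold = 0.35
    ),
    conn("S1-del", "S2-where-ex", rnd("S1-del", "S2-where-ex"),
      plastic = TRUE, bin_threshold = 0.35
    ),
    conn("S2-where-ex", "S2-where-inh", topo("S2-where-ex", "S2-where-inh", c(1L, 1L), c(1L, 1L))),
    conn("S2-where-inh", "S2-where-ex", wire_all_but_self(24L)),
    conn("S2-where-ex", "CLA-where", rnd("S2-where-ex", "CLA-where"),
      plastic = TRUE, supervised = TRUE, reward_window = "late",
      rate_scale = 8, bin_threshold = 0.75
    ),
    conn("S2-where-ex", "Attention", topo("S2-where-ex", "Attention", c(1L, 1L), c(1L, 1L))),
    conn("Attention", "S2-where-ex", wire_all_but_self(24L)),
    conn("Attention", "CLA-shape", att_to_clashape),
    conn("Attention", "Attention", wire_all_but_self(24L)),
    conn("CLA-where", "Target", wire_pools(net$pools$`CLA-where`, 80L, 8L)),
    conn("CLA-where", "Obstacle", wire_pools(net$pools$`CLA-where`, 80L, 8L)),
    conn("CLA-shape", "Shape-inh", wire_pools(net$pools$`CLA-shape`, 30L, 3L)),
    conn("CLA-shape", "Shape-decision", wire_pools(net$pools$`CLA-shape`, 30L, 3L)),
    conn("Shape-inh", "Target", shapeinh_to_target),
    conn("Shape-inh", "Obstacle", shapeinh_to_obstacle),
    conn("Shape-decision", "Target", matrix(1, 8, 3)),
    conn("Shape-decision", "Obstacle", matrix(1, 8, 3)),
    conn("Target", "Motor", motor_catch),
    conn("Obstacle", "Motor", motor_avoid)
  )
  names(cl) <- vapply(cl, function(cn) paste0(cn$source, "->", cn$target),
    character(1)
  )
  net$conns <- cl

  # Index plastic incoming connections per target layer (for simultaneous
  # per-layer renormalization) and mark trace-carrying source groups.
  net$plastic_in <- list()
  for (ci in seq_along(cl)) {
    cn <- cl[[ci]]
    if (cn$plastic) {
      net$plastic_in[[cn$target]] <- c(net$plastic_in[[cn$target]], ci)
      net$groups[[cn$source]]$has_trace <- TRUE
    }
  }

  zero_template <- lapply(net$groups, function(g) g$n)
  net$zero_input <- function(batch) {
    lapply(zero_template, function(n) matrix(0, n, batch))
  }

  net$state <- NULL
  net
}

#' @export
print.bn_network <- function(x, ...) {
  n_tot <- sum(vapply(x$groups, function(g) g$n, numeric(1)))
  cat(
    "<bn_network> ", length(x$groups), " groups, ", n_tot, " neurons, ",
    length(x$conns), " connections; weights ",
    if (x$binarized) "binary" else "real-valued", "\n",
    sep = ""
  )
  invisible(x)
}

#' Check a network against the digital-hardware constraints
#'
#' Verifies that every group's parameters lie within the settable ranges of
#' the target neuromorphic core (threshold 1--256, leak and synaptic
#' multipliers 0--255), that only two axon types are used, and -- for a
#' consolidated network -- that every plastic synapse is binary.
#'
#' @param net A `bn_network`.
#' @return An object of class `bn_hardware_report`: a tibble with one row
#'   per check (`scope`, `item`, `check`, `pass`, `detail`).
#' @export
validate_hardware <- function(net) {
  rows <- list()
  add <- function(scope, item, check, pass, detail = "") {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      scope = scope, item = item, check = check, pass = pass, detail = detail
    )
  }
  for (g in net$groups) {
    if (g$is_input) next
    add("group", g$name, "threshold_range", g$threshold >= 1 && g$threshold <= 256,
      paste0("T=", g$threshold)
    )
    add("group", g$name, "leak_range", g$leak >= -256 && g$leak <= 255,
      paste0("L=", g$leak)
    )
    add("group", g$name, "s_plus_range", g$s_plus >= 0 && g$s_plus <= 255,
      paste0("S+=", g$s_plus)
    )
    add("group", g$name, "s_minus_range", g$s_minus >= 0 && g$s_minus <= 255,
      paste0("S-=", g$s_minus)
    )
    add("group", g$name, "axon_type", g$axon_type %in% c("excitatory", "inhibitory"),
      g$axon_type
    )
    add("group", g$name, "reset_to_zero", TRUE, "reset semantics fixed by engine")
  }
  for (nm in names(net$conns)) {
    cn <- net$conns[[nm]]
    binary <- all(cn$W %in% c(0, 1))
    if (cn$plastic) {
      add("connection", nm, "binary_synapses", binary,
        if (binary) "binary" else "real-valued (pre-consolidation)"
      )
    } else {
      add("connection", nm, "binary_synapses", binary, "hard-wired")
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bn_hardware_report", class(out))
  out
}

#' @export
print.bn_hardware_report <- function(x, ...) {
  n_fail <- sum(!x$pass)
  cat("<hardware report> ", nrow(x), " checks, ", n_fail, " failing\n", sep = "")
  if (n_fail > 0) print(tibble::as_tibble(x)[!x$pass, ])
  invisible(x)
}

#' Sever the outputs of the attention module
#'
#' Zeroes all outgoing connections of the Attention group (the attention
#' lesion used to measure the contribution of top-down attentional
#' modulation). Everything else is untouched; severing twice equals severing
#' once. The input network is not modified; a lesioned copy is returned.
#'
#' @param net A trained `bn_network`.
#' @return A new `bn_network` with attention outputs removed.
#' @export
sever_attention <- function(net) {
  out <- clone_network(net)
  for (nm in names(out$conns)) {
    if (out$conns[[nm]]$source == "Attention") {
      out$conns[[nm]]$W[] <- 0
    }
  }
  out
}

#' Deep-copy a network
#'
#' @param net A `bn_network`.
#' @return An independent copy sharing no state with `net`.
#' @export
clone_network <- function(net) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(net, all.names = TRUE)) {
    assign(nm, get(nm, envir = net), envir = out)
  }
  out$state <- NULL
  class(out) <- "bn_network"
  out
}

#' Total neuron count of a network
#'
#' @param net A `bn_network`.
#' @return Integer.
#' @export
network_size <- function(net) {
  sum(vapply(net$groups, function(g) g$n, numeric(1)))
}
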