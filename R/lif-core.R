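#' One membrane update for a population of hardware-constrained LIF neurons
#'
#' Implements the discrete-time (1 ms tick) membrane dynamics of a digital
#' LIF neuron with linear leak and reset-to-zero. On each tick the weighted
#' excitatory input `x` and inhibitory input `y` are integrated together
#' with the linear leak in a single combined update, the result is clamped
#' below at 0, and the candidate potential is compared with the firing
#' threshold (strictly greater than):
#'
#' \deqn{V = \max(0,\, M + x - y - L)}
#' \deqn{\mathrm{fired} = (V > T)}
#' \deqn{M' = 0 \text{ if fired, else } V}
#'
#' Clamping before the threshold test keeps the membrane non-negative at
#' every observable point; a neuron that fires has membrane exactly 0 at
#' the start of the next tick.
#'
#' @param M Numeric vector (or matrix) of non-negative membrane potentials.
#' @param x Weighted excitatory input, `s_plus *` (weighted spike count);
#'   same shape as `M`. Must be non-negative.
#' @param y Weighted inhibitory input, `s_minus *` (weighted spike count);
#'   same shape as `M`. Must be non-negative.
#' @param params A [neuron_group_params()] object.
#'
#' @return A list with elements `M` (updated membrane, same shape as the
#'   input) and `fired` (logical, same shape).
#' @export
#' @examples
#' p <- neuron_group_params(threshold = 1, leak = 2, s_plus = 32, s_minus = 0)
#' membrane_step(0, x = 32, y = 0, params = p) # candidate 30 > 1: fires
membrane_step <- function(M, x, y, params) {
  if (any(x < 0) || any(y < 0)) {
    stop("weighted inputs `x` and `y` must be non-negative", call. = FALSE)
  }
  V <- M + x - y - params$leak
  V[V < 0] <- 0
  fired <- V > params$threshold
  V[fired] <- 0
  list(M = V, fired = fired)
}

#' Propagate a spike vector through a synapse matrix
#'
#' Computes the weighted input each target neuron will integrate on the
#' *next* tick (every spike is integrated by its postsynaptic neurons in the
#' following cycle).
#'
#' @param spikes Logical or 0/1 numeric vector of source-group spikes, or an
#'   `n_source x batch` matrix for batched simulation.
#' @param synapses Weight matrix with `n_target` rows and `n_source` columns.
#'
#' @return Numeric vector (or `n_target x batch` matrix) of per-target
#'   weighted input.
#' @export
#' @examples
#' W <- matrix(c(1, 0.5, 1), nrow = 1) # one target, three sources
#' propagate(c(1, 1, 0), W) # 1.5
propagate <- function(spikes, synapses) {
  if (is.matrix(spikes)) {
    if (ncol(synapses) != nrow(spikes)) {
      stop("synapse matrix has ", ncol(synapses), " source columns but ",
        nrow(spikes), " source spikes were given",
        call. = FALSE
      )
    }
    return(synapses %*% spikes)
  }
  if (ncol(synapses) != length(spikes)) {
    stop("synapse matrix has ", ncol(synapses), " source columns but ",
      length(spikes), " source spikes were given",
      call. = FALSE
    )
  }
  drop(synapses %*% as.numeric(spikes))
}

# ---------------------------------------------------------------------------
# Internal simulation state
#
# A simulation state holds, per group, an n x B membrane matrix and the 0/1
# spike matrix emitted on the previous tick (B = number of independent
# parallel trials sharing the same weights; training uses B = 1). Delayed
# connections keep a ring buffer of source spike matrices.
# ---------------------------------------------------------------------------

bn_init_state <- function(net, batch = 1L) {
  st <- new.env(parent = emptyenv())
  st$batch <- as.integer(batch)
  st$M <- lapply(net$groups, function(g) matrix(0, g$n, batch))
  st$spk <- lapply(net$groups, function(g) matrix(0, g$n, batch))
  st$buf <- lapply(net$conns, function(cn) {
    if (cn$delay > 0L) {
      src_n <- net$groups[[cn$source]]$n
      replicate(cn$delay, matrix(0, src_n, batch), simplify = FALSE)
    } else {
      NULL
    }
  })
  st$traces <- lapply(net$groups, function(g) {
    if (isTRUE(g$has_trace)) matrix(0, g$n, batch) else NULL
  })
  st$tick <- 0L
  st
}

# Advance the whole network by one tick. `frame` is a length-100 0/1 vector
# (or 100 x B matrix) clamped onto the retina. Spikes produced at tick t are
# visible to targets at tick t + 1 (+ any extra configured delay).
# `testing = TRUE` skips train-only groups. Returns the list of spike
# matrices emitted this tick.
bn_tick <- function(net, st, frame, testing = FALSE) {
  groups <- net$groups
  conns <- net$conns
  spk_prev <- st$spk
  newspk <- spk_prev # reuse shape
  newM <- st$M

  # Gather per-group weighted input from spikes of the previous tick.
  exc <- vector("list", length(groups))
  names(exc) <- names(groups)
  inh <- exc
  for (ci in seq_along(conns)) {
    cn <- conns[[ci]]
    if (testing && groups[[cn$source]]$train_only) next
    if (cn$delay > 0L) {
      buf <- st$buf[[ci]]
      s <- buf[[1L]]
      st$buf[[ci]] <- c(buf[-1L], list(spk_prev[[cn$source]]))
    } else {
      s <- spk_prev[[cn$source]]
    }
    contrib <- cn$W %*% s
    tg <- cn$target
    if (cn$sign == "excitatory") {
      exc[[tg]] <- if (is.null(exc[[tg]])) contrib else exc[[tg]] + contrib
    } else {
      inh[[tg]] <- if (is.null(inh[[tg]])) contrib else inh[[tg]] + contrib
    }
  }

  for (gn in names(groups)) {
    g <- groups[[gn]]
    if (g$is_input) {
      # Retina neurons are input clamps: they spike wherever the frame is 1.
      newspk[[gn]] <- if (is.matrix(frame)) frame else matrix(frame, g$n, st$batch)
      next
    }
    if (testing && g$train_only) {
      newspk[[gn]] <- matrix(0, g$n, st$batch)
      next
    }
    # Inlined membrane update (see membrane_step() for the contract).
    V <- st$M[[gn]]
    e <- exc[[gn]]
    if (!is.null(e)) V <- V + g$s_plus * e
    i <- inh[[gn]]
    if (!is.null(i)) V <- V - g$s_minus * i
    V <- V - g$leak
    V[V < 0] <- 0
    fired <- V > g$threshold
    V[fired] <- 0
    newM[[gn]] <- V
    newspk[[gn]] <- fired + 0
  }

  st$M <- newM
  st$spk <- newspk
  st$tick <- st$tick + 1L
  newspk
}

#' Advance a built network by one tick on a retina frame
#'
#' Runs a single 1 ms simulation tick: every group integrates the weighted
#' input produced by spikes of the previous tick, applies the LIF membrane
#' update, and queues its spikes for the next tick. Retina neurons spike
#' wherever the frame pixel is 1. The network keeps its simulation state
#' between calls; use [reset_network()] to clear it.
#'
#' @param net A network built by [build_network()].
#' @param frame A 10x10 0/1 matrix (or vector of length 100, column-major).
#' @param testing Logical; if `TRUE`, train-only groups are disconnected.
#'
#' @return Invisibly, a tibble with one row per spike emitted this tick
#'   (columns `tick`, `group`, `neuron`).
#' @export
network_tick <- function(net, frame, testing = FALSE) {
  stopifnot(inherits(net, "bn_network"))
  if (is.null(net$state)) net$state <- bn_init_state(net, 1L)
  f <- as.numeric(frame)
  if (length(f) != net$groups[[net$retina]]$n) {
    stop("frame has ", length(f), " pixels; the retina expects ",
      net$groups[[net$retina]]$n,
      call. = FALSE
    )
  }
  spk <- bn_tick(net, net$state, f, testing = testing)
  rows <- purrr::map_dfr(names(spk), function(gn) {
    idx <- which(spk[[gn]][, 1] > 0)
    if (!length(idx)) {
      return(NULL)
    }
    tibble::tibble(tick = net$state$tick, group = gn, neuron = idx)
  })
  invisible(rows)
}

#' Reset the per-trial simulation state of a network
#'
#' Clears membranes, pending spikes, delay buffers and burstiness traces.
#' Weights are untouched.
#'
#' @param net A network built by [build_network()].
#' @return The network, invisibly.
#' @export
reset_network <- function(net) {
  stopifnot(inherits(net, "bn_network"))
  net$state <- NULL
  invisible(net)
}
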