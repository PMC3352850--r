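#' Update presynaptic burstiness traces
#'
#' The burstiness of a presynaptic neuron is a memory trace of its recent
#' spiking: every spike increments the trace by `trace_increment` and the
#' trace decays linearly by `trace_decay` each tick, clamped below at 0 (no
#' upper bound is enforced). Increment and decay are applied in a single
#' per-tick update,
#' `b' = max(0, b + trace_increment * spike - trace_decay)`.
#'
#' @param traces Non-negative numeric vector (or matrix) of traces.
#' @param pre_spikes Logical or 0/1 numeric, same shape as `traces`.
#' @param cfg A [plasticity_config()].
#'
#' @return Updated traces, same shape.
#' @export
#' @examples
#' cfg <- plasticity_config()
#' b <- update_burst_traces(0, 1, cfg) # 0.35
#' update_burst_traces(b, 0, cfg) # 0.30
update_burst_traces <- function(traces, pre_spikes, cfg) {
  pmax(traces + cfg$trace_increment * (pre_spikes + 0) - cfg$trace_decay, 0)
}

#' Apply a burst-STDP weight update for this tick's postsynaptic spikes
#'
#' For every postsynaptic neuron that spiked this tick, each of its incoming
#' plastic weights changes by `delta_w = rate * b_pre`, where `b_pre` is the
#' presynaptic burstiness trace. Weights are clamped to
#' `[weight_lower, weight_upper]`. Non-spiking targets are unchanged. With a
#' positive rate this is the potentiation-only unsupervised rule; value-gated
#' learning passes a signed rate.
#'
#' @param weights `n_target x n_source` weight matrix of a plastic
#'   connection.
#' @param traces Length-`n_source` presynaptic burstiness traces.
#' @param post_spikes Logical or 0/1 numeric vector of length `n_target`.
#' @param rate Signed learning rate (base rate, possibly multiplied by a
#'   value-gating modulation).
#' @param cfg A [plasticity_config()] supplying the weight bounds.
#'
#' @return The updated weight matrix.
#' @export
burst_stdp_update <- function(weights, traces, post_spikes, rate, cfg) {
  idx <- which(as.logical(post_spikes))
  if (!length(idx)) {
    return(weights)
  }
  delta <- rate * as.numeric(traces)
  weights[idx, ] <- weights[idx, , drop = FALSE] +
    matrix(delta, length(idx), length(delta), byrow = TRUE)
  weights[idx, ] <- pmin(pmax(weights[idx, , drop = FALSE], cfg$weight_lower),
    cfg$weight_upper
  )
  weights
}

#' Value-gated learning-rate modulation with simulated annealing
#'
#' An external supervisor judges each response; correct responses yield a
#' positive modulation (annealed from `reward_start` to `reward_end`) and
#' wrong responses a non-positive one (annealed from `punish_start` to
#' `punish_end`, i.e. to no change). The signed learning rate is
#' `eta = eta0 * v(reward, progress)` with linear interpolation in the
#' fraction of completed training presentations.
#'
#' @param eta0 Base (unsigned) learning rate.
#' @param reward_correct Logical; was the judged response correct?
#' @param progress Fraction of the annealing horizon completed, in `[0, 1]`.
#' @param schedule A [reward_schedule()].
#'
#' @return The signed learning rate.
#' @export
#' @examples
#' s <- reward_schedule()
#' value_gated_rate(1, TRUE, 0, s) # 0.5
#' value_gated_rate(1, FALSE, 0, s) # -0.1
#' value_gated_rate(1, FALSE, 1, s) # 0
value_gated_rate <- function(eta0, reward_correct, progress, schedule) {
  progress <- min(max(progress, 0), 1)
  v <- if (isTRUE(reward_correct)) {
    schedule$reward_start +
      progress * (schedule$reward_end - schedule$reward_start)
  } else {
    schedule$punish_start +
      progress * (schedule$punish_end - schedule$punish_start)
  }
  eta0 * v
}

#' Homeostatic renormalization of a neuron's incoming weights
#'
#' Linearly rescales an incoming weight vector so that its largest element
#' becomes exactly 1, preserving the ordering and all pairwise ratios. An
#' all-zero vector is returned unchanged.
#'
#' @param weights Non-negative numeric vector of one neuron's incoming
#'   plastic weights.
#' @return The rescaled vector.
#' @export
#' @examples
#' renormalize_incoming(c(0.2, 0.5, 1.25)) # 0.16 0.40 1.00
renormalize_incoming <- function(weights) {
  m <- max(weights)
  if (m <= 0) {
    return(weights)
  }
  weights / m
}

#' Threshold weights to binary values
#'
#' Before testing, plastic weights are snapped to \{0, 1\}: a weight becomes
#' 1 when it is greater than or equal to the threshold, 0 otherwise.
#'
#' @param weights Numeric vector or matrix of weights in
#'   `[0, weight_upper]`.
#' @param threshold Binarization threshold in (0, 1).
#' @return Weights of the same shape with values in \{0, 1\}.
#' @export
binarize_weights <- function(weights, threshold = 0.5) {
  out <- (weights >= threshold) + 0
  if (is.matrix(weights)) dim(out) <- dim(weights)
  out
}

# Renormalize all plastic incoming connections of one layer simultaneously:
# for each target neuron the maximum is taken across *all* its plastic
# incoming connections, so the layer's strongest synapse per neuron is 1.
bn_renormalize_layer <- function(net, layer) {
  idx <- net$plastic_in[[layer]]
  if (is.null(idx) || !length(idx)) {
    return(invisible(net))
  }
  mats <- lapply(net$conns[idx], function(cn) cn$W)
  row_max <- do.call(pmax, lapply(mats, function(W) apply(W, 1, max)))
  scale <- ifelse(row_max > 0, 1 / row_max, 1)
  for (ci in idx) {
    net$conns[[ci]]$W <- net$conns[[ci]]$W * scale
  }
  invisible(net)
}
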