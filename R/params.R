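#' Neuron-group parameters for a hardware-constrained LIF population
#'
#' Bundles the per-layer settable parameters of a digital neuromorphic LIF
#' neuron: firing threshold, linear membrane leak, the excitatory and
#' inhibitory synaptic multipliers, and the axon type of the group's output.
#' All values are integers within the bit-width ranges of the target
#' hardware (threshold 1--256, leak and multipliers 0--255).
#'
#' @param threshold Firing threshold `T` (integer, 1--256). A neuron fires on
#'   a tick when its integrated membrane potential reaches `T`.
#' @param leak Linear per-tick membrane decrement `L` (integer, 0--255).
#' @param s_plus Multiplier applied to the summed weighted excitatory input
#'   (integer, 0--255).
#' @param s_minus Multiplier applied to the summed weighted inhibitory input
#'   (integer, 0--255); the product is subtracted from the membrane.
#' @param axon_type `"excitatory"` or `"inhibitory"`: the sign this group's
#'   output spikes carry at their targets.
#' @param train_only Logical; if `TRUE` the group is simulated during
#'   training and disconnected (outputs severed) during testing.
#'
#' @return An object of class `bn_group_params` (a named list).
#' @export
#' @examples
#' neuron_group_params(threshold = 31, leak = 16, s_plus = 16, s_minus = 0)
neuron_group_params <- function(threshold, leak, s_plus, s_minus,
                                axon_type = c("excitatory", "inhibitory"),
                                train_only = FALSE) {
  axon_type <- match.arg(axon_type)
  stopifnot(
    length(threshold) == 1, threshold >= 1, threshold <= 256,
    length(leak) == 1, leak >= 0, leak <= 255,
    length(s_plus) == 1, s_plus >= 0, s_plus <= 255,
    length(s_minus) == 1, s_minus >= 0, s_minus <= 255,
    is.logical(train_only), length(train_only) == 1
  )
  structure(
    list(
      threshold = as.numeric(threshold), leak = as.numeric(leak),
      s_plus = as.numeric(s_plus), s_minus = as.numeric(s_minus),
      axon_type = axon_type, train_only = train_only
    ),
    class = "bn_group_params"
  )
}

#' Plasticity constants for burst-STDP learning
#'
#' @param trace_increment Increment of the presynaptic burstiness trace on
#'   every spike (default 0.4).
#' @param trace_decay Linear decay of the trace at every tick (default 0.05).
#' @param base_rate Base learning rate `eta0` for weight updates (default
#'   0.01; calibrated so that a winning neuron's in-use weights reach the
#'   upper weight bound roughly once per sleep interval, the regime in
#'   which renormalization prunes stale synapses -- see the methods
#'   vignette). Per-connection multipliers scale it per learning system.
#' @param weight_lower,weight_upper Bounds on synaptic strength during
#'   training (defaults 0 and 1.5).
#' @param binarize_threshold Threshold used to snap weights to \{0, 1\}
#'   before testing (default 0.5; weights `>=` threshold become 1).
#'
#' @return An object of class `bn_plasticity_config`.
#' @export
plasticity_config <- function(trace_increment = 0.4, trace_decay = 0.05,
                              base_rate = 0.01,
                              weight_lower = 0, weight_upper = 1.5,
                              binarize_threshold = 0.5) {
  stopifnot(
    trace_increment > trace_decay, trace_decay > 0,
    base_rate > 0,
    weight_lower < binarize_threshold, binarize_threshold < weight_upper
  )
  structure(
    list(
      trace_increment = trace_increment, trace_decay = trace_decay,
      base_rate = base_rate,
      weight_lower = weight_lower, weight_upper = weight_upper,
      binarize_threshold = binarize_threshold
    ),
    class = "bn_plasticity_config"
  )
}

#' Annealed reward/punishment schedule for value-gated learning
#'
#' The external supervisor multiplies the accumulated burst-STDP change by a
#' signed modulation: a positive reward constant for correct responses and a
#' non-positive punishment constant for wrong ones. Both constants are
#' annealed linearly over the training presentations: the reward shrinks from
#' `reward_start` to `reward_end` and the punishment from `punish_start` up
#' to `punish_end` (0, i.e. late errors are simply ignored).
#'
#' @param reward_start,reward_end Reward modulation at the start/end of
#'   annealing (defaults 0.5 and 0.1).
#' @param punish_start,punish_end Punishment modulation at the start/end of
#'   annealing (defaults -0.1 and 0).
#' @param anneal_horizon Number of training presentations over which the
#'   constants interpolate (default 400).
#'
#' @return An object of class `bn_reward_schedule`.
#' @export
reward_schedule <- function(reward_start = 0.5, reward_end = 0.1,
                            punish_start = -0.1, punish_end = 0,
                            anneal_horizon = 400) {
  stopifnot(
    reward_start > 0, reward_end > 0,
    punish_start <= 0, punish_end <= 0,
    abs(reward_end) <= abs(reward_start),
    abs(punish_end) <= abs(punish_start),
    anneal_horizon >= 1
  )
  structure(
    list(
      reward_start = reward_start, reward_end = reward_end,
      punish_start = punish_start, punish_end = punish_end,
      anneal_horizon = as.integer(anneal_horizon)
    ),
    class = "bn_reward_schedule"
  )
}
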