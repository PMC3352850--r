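---
title: "Methods: hardware-constrained spiking networks with burst-STDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hardware-constrained spiking networks with burst-STDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`neuroburst` simulates a small visual system built entirely from
digital-hardware-compatible leaky integrate-and-fire (LIF) neurons and binary
synapses, trained offline with burst-STDP, value gating and homeostatic
renormalization. This vignette documents the model, the numerical and design
choices the package makes where the architecture leaves them open, and the
known limitations of the implementation. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## The neuron model

Every neuron is a discrete-time LIF unit updated once per 1 ms tick:

$$V \leftarrow \max(0,\; M + S^{+}X - S^{-}Y - L), \qquad
  \text{fire if } V > T,\ \text{then } M \leftarrow 0, \text{ else } M \leftarrow V.$$

`X` and `Y` are the weighted excitatory and inhibitory spike inputs from the
previous tick (every spike reaches its targets one cycle later), `L` is a
linear (not proportional) leak, and the membrane is clamped below at zero.
Parameters are integers within the settable ranges of a digital neuromorphic
core: threshold 1–256, leak and the two per-neuron synaptic multipliers
0–255, two axon types, reset-to-zero. `validate_hardware()` checks every
group and, after consolidation, the binarity of every plastic synapse.

The combined add/leak/clamp/threshold order above is one of two defensible
readings of a hardware LIF pipeline (the other tests the threshold before
subtracting the leak). We simulated both: with the threshold-first order all
suprathreshold layers fire in lock-step on the same tick, so the
winner-take-all (WTA) circuits can never single out a first-crossing winner
and unsupervised learning collapses onto uniform weights. The adopted order
lets membranes accumulate over 2–5 ticks with heterogeneous slopes, which is
what the competitive learning in this architecture needs. Ties (`V == T`) do
not fire.

## Plasticity

*Burst-STDP.* Each presynaptic neuron carries a burstiness trace
`b <- max(0, b + 0.4·spike - 0.05)` (one trace per neuron, shared by its
outgoing plastic synapses). On every postsynaptic spike, each incoming
plastic weight changes by `eta · b_pre`, clamped to `[0, 1.5]`. Unsupervised
learning is potentiation-only.

*Value gating.* An external supervisor judges each presentation: the winning
classifier pool is the one with the largest integrated spike count; ties
produce no reward event. Connections onto the label pool's firing neurons
are rewarded and connections onto firing neurons of competing pools are
punished; the reward constant anneals 0.5 to 0.1 and the punishment
-0.1 to 0 over the supervised stage. Label-pool neurons that stayed silent
receive a small teacher update (their class's window-integrated presynaptic
trace, scaled by 0.25): spike-gated eligibility alone cannot recover a pool
whose weights have fallen below its firing threshold, and without this term
single pools occasionally die irreversibly during training.

*Renormalization ("sleep").* At per-layer intervals, all plastic incoming
weights of a layer are rescaled per neuron so the strongest synapse is 1.
Intervals are means; each inter-sleep gap is drawn uniformly within ±50%,
which also injects the only exploration the otherwise rhythm-locked
noiseless dynamics get. Renormalization prunes stale synapses only while a
neuron's in-use weights actually grow toward the 1.5 bound between sleeps;
the per-stream learning rates are therefore calibrated (base rate 0.01 with
per-connection multipliers: 0.1 for the shape feature stream, 1 for the
motion stream, 4–8 for the classifiers) so that the bound is reached roughly
once per sleep. Rates much larger than this flatten all ratios against the
bound and renormalization stops discriminating; much smaller rates never
reach the bound and stale weights are never pruned.

*Consolidation.* After training, weights are renormalized once more and
thresholded to {0, 1}. The threshold is per connection: 0.5 by default,
0.35 for the motion feature connections (keeping each cell's full
edge-segment window group, which behaves as a noise-robust n-of-m detector),
0.65 for the shape features and 0.6–0.75 for the classifiers (keeping only
decisively learned synapses).

## Architecture

The 23 neuron groups (766 neurons) form five modules: a 10x10 retina of
input clamps; a shape stream (two-orientation edge detectors S1, max-pooling
complex cells C1 with localized inhibitory feedback, a competitive feature
layer S2 and a 3-pool classifier); a motion stream (instantaneous and
delayed presence detectors over 4x4 retinal windows, a competitive S2 layer
reading both, and an 8-pool trajectory classifier); an attention layer that
is a conjunction detector of hard-wired topographic motion input and learned
shape input, with inhibitory feedback to the motion S2 layer and to the
non-target classifier pools; and a decision module (Target/Obstacle relays
gated per letter by Shape-inh, a Shape-decision consistency integrator, and
8 motor neurons, one per catcher placement).

Wiring choices the layer table leaves open, as shipped:

* S1 edge detectors read non-overlapping retina pixel pairs (stride 2 along
  the paired axis), the unique tiling consistent with the printed grids.
* C1 inhibitory cells suppress a 3x3 neighbourhood (centre excluded) with
  one extra tick of delay. The edge response under a constant stimulus is
  period-2; without the extra delay the feedback lands exactly on the next
  response tick and the legitimate edge responses annihilate each other,
  silencing the shape stream entirely. With it, suppression lands on the
  opposite phase: steady rhythmic responses pass, dense every-tick (noise)
  activity is still clipped.
* The S2 WTA layers inhibit all cells except their own source.
* Classifier pools are the grid rows: 3 letter pools, 8 trajectory pools.
* Target k reads trajectory pool k and drives motor k (the catch placement);
  Obstacle k drives the diagonally opposite motor (the avoidance placement).
  Shape-inh's letter rows gate the two pathways: the target letter silences
  Obstacle, the avoidance letter and the distractor silence Target. Routing
  the distractor through the avoidance pathway (rather than silencing both)
  is required by the motion-detection experiment, which draws all three
  letters and reads the direction decision from the motor layer; the
  "distractor elicits no response" behaviour holds only for the object task
  convention in outcome scoring.
* The trajectory classifier is judged, and its eligibility accumulated, on
  an arrival window (movement steps 4–8 of 10): the motion S2 cells are
  position-coded, so the trajectory (edge and direction) is recoverable as
  which cells fire *last*, not which fire at all.

## The environment

Letters T, L and J are 4x4 glyphs with 2-pixel strokes (12 on-pixels). A
3x3 glyph cannot reach the 7-pixel count a motion window needs to respond at
all, so the glyph scale is set by the motion stream's printed threshold.
Objects appear fully visible in a corner, advance 1 pixel every 10 ticks
laterally or vertically (8 trajectories), and leave the field after 100
ticks; the delayed motion pathway lags by the same 10 ticks. Noise flips
every pixel independently with probability `p`, redrawn each tick. Training
presentations are single objects; the unsupervised stage adds 1% exploration
noise (see Limitations), the supervised stage is noiseless.

## Training protocol

`train_standard_network()` runs a staged protocol per epoch: 400
unsupervised presentations (feature layers learn under WTA competition),
consolidation of the feature connections to binary, then 900 supervised
presentations under *test dynamics* (train-only WTA layers disconnected,
binary features) so the classifiers learn exactly the activity statistics
they will face at test, and finally full consolidation. A concurrent
(non-staged) mode remains available through `train_network()`; in our
simulations it consistently produced classifiers mismatched to the test-time
activity regime.

## Problem sizes

The shipped defaults are desk-scale: one epoch is 1,300 presentations of
100 ticks each (about 75 s on one CPU core); the shape experiment trains 4
networks; each sweep level is a 100-trial battery run as one batched
simulation. `scripts/acceptance.R` reruns the full set of experiments in
roughly 5-6 minutes.

## Known limitations

This implementation does not reach the recognition and robustness levels
the architecture is capable of in its original form; the acceptance script
reports what it actually measures, and several headline quantities fall well
short. The root causes, established by simulation during development:

* Under deterministic noiseless dynamics the network is phase-locked to the
  stimulus onset (period-2 rhythms everywhere), so WTA races resolve
  identically on every trial. Winners chain across a stimulus's movement:
  whichever cell wins one window pattern carries potentiated overlap weights
  into the next, and feature cells converge to position unions rather than
  the sharp direction-selective window pairs the design intends. Set-level
  analysis shows this is structural: with the printed S2 parameters, firing
  requires at least 3 co-active windows while adjacent patterns and
  opposite-direction patterns overlap in 2-3 windows, so any cell that fires
  at all eventually fires for both directions of its edge. The sleep-timing
  jitter and the small unsupervised-stage exploration noise mitigate but do
  not eliminate this.
* Direction information therefore survives mainly in response *timing*
  (arrival-side cells fire last), which the arrival-window classifier and
  the last-response motor rule exploit; a linear readout ceiling measured on
  the feature counts bounds trajectory classification well below the
  original system's reported levels, and the motor pathway inherits that
  ceiling.
* Classifier pools occasionally collapse (a pool that falls silent loses all
  spike-gated eligibility); the teacher term prevents irreversible death but
  per-seed variance in pool quality remains large.

Four cells of the layer parameter table are adjusted relative to the
original design, each because the printed value is provably non-functional
under the adopted membrane-update order (details in the source): the shape
WTA inhibitory layer's leak (32 to 2: its only input exactly cancels,
so it could never fire), the Target/Obstacle leak (5 to 2: the classifier
pools burst at most every other tick, and a leak of 5 exactly absorbs the
maximal pool input, leaving the relays permanently silent), and the motor
multiplier (4 to 16, with the shape-consistency drive rerouted to
Target/Obstacle: an exact-tick conjunction at the motor is unrealizable
because the two pathways' period-2 spike phases never coincide). All
adjusted values remain within the hardware parameter ranges.

What passing the synthetic tests does and does not show: the environment
exercises translation across a tiny binary retina with independent
pixel-flip noise. It does not test scale or rotation invariance, gray-scale
contrast, correlated noise, occlusion, or more than two simultaneous
objects, and conclusions about natural images are out of reach by design.
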