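# neuroburst

`neuroburst` is a desk-scale simulator for spiking neural networks under
digital neuromorphic hardware constraints. It is aimed at computational
neuroscientists and neuromorphic-hardware researchers who want to study how
much visual behaviour a *minimal* network — fewer than 1000 leaky
integrate-and-fire (LIF) neurons with binary synapses and a handful of
integer parameters per neuron — can learn with biologically inspired
plasticity, entirely in software and reproducibly from a seed.

## The model

Every neuron follows a 1 ms discrete-time LIF update with linear leak,
reset-to-zero, and a one-cycle spike propagation delay:

$$V \leftarrow \max(0,\ M + S^{+}X - S^{-}Y - L),\qquad
\text{fire if } V > T.$$

Learning combines three mechanisms:

* **burst-STDP** — each presynaptic neuron keeps a burstiness trace
  $b \leftarrow \max(0,\ b + 0.4\,s - 0.05)$; every postsynaptic spike
  potentiates incoming weights by $\eta\, b_{\text{pre}}$, clamped to
  $[0, 1.5]$;
* **value gating** — an external supervisor rewards or punishes the
  classifier connections that contributed to each response, with constants
  annealed from $0.5$ to $0.1$ (reward) and $-0.1$ to $0$ (punishment);
* **homeostatic renormalization** — at per-layer "sleep" intervals each
  neuron's incoming plastic weights are rescaled so the strongest equals 1,
  which progressively prunes unused synapses and drives weights toward the
  binary values the hardware requires; a final threshold snaps them to
  {0, 1}.

These pieces are assembled into a 23-group architecture: a 10x10 binary
retina, an HMAX-like shape stream (edge detectors, max pooling,
winner-take-all feature learning, a letter classifier), a delay-line motion
stream (instantaneous + delayed window detectors, motion feature cells, a
trajectory classifier), a top-down attention layer, and a motor decision
module that places a "catcher": in front of an arriving target letter (T),
opposite an avoidance letter (L), and ideally nowhere for a distractor (J).
The synthetic environment moves 4x4 letter glyphs along 8 corner/direction
trajectories with independent per-pixel flip noise.

## A worked example

```r
library(neuroburst)

net <- build_network(seed = 1)
net
#> <bn_network> 23 groups, 766 neurons, 37 connections; weights real-valued

# one epoch: 400 unsupervised presentations, feature consolidation,
# 900 value-gated presentations under test dynamics, final binarization
net <- train_standard_network(seed = 1)

sw <- noise_sweep(net, "single_object",
  levels = c(0, 0.08, 0.20), n_per_level = 100, seed = 42)
tibble::as_tibble(sw)[, c("noise", "n", "correct", "incorrect", "no_decision")]
#> # A tibble: 3 x 5
#>   noise     n correct incorrect no_decision
#>   <dbl> <dbl>   <int>     <int>       <int>
#> 1  0      100      18        54          28
#> 2  0.08   100       9        23          68
#> 3  0.2    100       4         8          88
```

Each row is a 100-trial battery of single moving letters (T or L,
random corner and direction) at one pixel-flip noise level. A trial is
**Correct** when the last motor spike before the object exits matches the
expected catcher placement, **Incorrect** when it does not, and
**NoDecision** when no motor neuron fired. (As the numbers show, the trained
network responds but its placement accuracy is limited; the methods
vignette's *Known limitations* section analyses why the learned motion code
falls short of what this architecture is designed to achieve.) Results are
tibbles: `tidy()`, `glance()` and `autoplot()` give long-format fractions,
per-arm summaries and the stacked-outcome figure. `validate_hardware(net)`
reports every parameter-range and synapse-binarity check, and
`save_network()` / `load_network()` round-trip a network through a JSON
archive exactly.

A thin command-line wrapper ships in `inst/scripts/neuroburst`
(`build`, `train`, `sweep`, `ablate`, `export-hw`), driven by a YAML run
configuration.

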