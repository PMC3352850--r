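Package: neuroburst
Title: Hardware-Constrained Spiking Neural Networks with Burst-STDP Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale simulator for digital-neuromorphic spiking neural
    networks. Provides discrete-time (1 ms tick) leaky integrate-and-fire
    neurons under digital-hardware constraints (integer parameters, linear
    leak, reset-to-zero, binary synapses, two axon types), burst-STDP
    plasticity with value-gated reward modulation and homeostatic
    renormalization that drives synapses to binary values, a hierarchical
    visual architecture (HMAX-like shape stream, delay-line motion stream,
    top-down attention, and a motor decision module), a synthetic 10x10
    moving-letter environment with pixel-flip noise, and the training and
    evaluation protocols for shape recognition, motion detection, noise
    tolerance, and attention-ablation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
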