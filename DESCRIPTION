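Package: embodiedGH
Title: Embodied Greenberg-Hastings Connectome Simulator with Homeostatic
    Balancing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates an excitable three-state (Greenberg-Hastings) network
    on a weighted structural connectome, embodied as an agent exploring a
    bounded two-dimensional arena through a closed sensorimotor loop.
    Implements two homeostatic mechanisms -- local inhibitory-threshold
    plasticity driving each node toward a target firing rate, and a
    macroscopic task-negative balancing rule that keeps the count of
    exogenously activated nodes constant -- together with an analysis suite:
    neuronal-avalanche detection, least-squares power-law fits, the kappa
    deviation statistic against a -3/2 reference law, movement entropy,
    box-counting fractal dimension of trajectories, and brain-environment
    correlation metrics. Config-driven experiment runners reproduce
    coupling-by-threshold phase sweeps, learning-rate-by-target-rate
    homeostasis sweeps, and multi-variant behavioral comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
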