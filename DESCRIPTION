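Package: hybridspike
Title: Rate-Independent Hybrid Spike Message Passing for Distributed
    Spiking-Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the communication cost of spike exchange in
    distributed spiking neural network simulations. Implements address-event
    representation (AER) and bit-packed spike packet codecs together with a
    hybrid scheme that switches between them per projection and per time step
    at a configurable pivot point, network partitioning with dummy-neuron
    registries, Poisson spike-train generation with validation statistics,
    a loopback spike-exchange layer with word-level cost accounting, and a
    strong/weak scaling benchmark harness with a worked packet-size example
    for a 576-neuron basal-ganglia population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
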