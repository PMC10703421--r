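Package: mitosim
Title: Agent-Based Stochastic Simulation of Mitochondrial Network Dynamics
    and Asymmetric Aggregate Inheritance in Budding Yeast
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the budding-yeast mitochondrial network as indivisible
    2D particles in a periodic box that diffuse as rigid bodies and undergo
    volume-conditioned fission and fusion, with optional marking of particles
    by protein aggregates (DUMPs) and biased placement of fission at the
    aggregate boundary.  Implements the two-step graph-based inheritance
    algorithm (largest network, breadth-first selection from the tip of its
    longest branch) and the accompanying analytics: bootstrap inheritance
    probabilities, DUMP cluster counting, mean-squared-displacement diffusion
    estimation, event-rate downsampling to experimental frame rates, and
    bias-fraction sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
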