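Package: tcrelay
Title: Thalamocortical Relay Neuron Simulation and Key-Parameter Fitting by
    Chaotic-Inertia Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a single-compartment conductance-based thalamocortical
    (TC) relay neuron with leak, sodium, potassium and low-threshold calcium
    (T-type) currents, scores its relay reliability against pulse-train inputs,
    and recovers the three key parameters governing the Parkinsonian relay
    regime (the pallidal inhibitory drive, the T-current conductance and its
    reversal potential) by particle swarm optimization. The optimizer switches
    each particle's inertia weight between a nonlinear concave schedule and a
    Logistic chaotic map according to the particle's fitness relative to the
    swarm mean; four classical inertia schemes (constant, linear and two
    concave schedules) are included for comparison. Fitness is a weighted sum
    of squared differences in four spike-train features: relay reliability,
    spike count, mean spike peak and mean subthreshold voltage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
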