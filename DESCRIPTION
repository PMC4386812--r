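Package: nlif
Title: Reduced Integrate-and-Fire Models of Auditory Coincidence Detector Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reduced conductance-based integrate-and-fire models of
    the barn owl's nucleus laminaris coincidence detector neurons: a
    two-compartment active model with a somatic low-voltage-activated
    potassium (KLVA) conductance and a nodal spike generator, a
    single-compartment active model, a single-compartment passive model, and
    a non-spiking subthreshold variant. Provides stochastic phase-locked
    binaural synaptic input (inhomogeneous Poisson fibers filtered through an
    alpha-function synapse), steady-state and small-signal membrane analysis,
    and a suite of evaluation protocols: average spike shape, step-current
    response classification, rate versus interaural phase difference curves,
    threshold and refractory-period robustness sweeps, and a forward-Euler
    time-step reliability test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
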