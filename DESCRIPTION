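Package: cerebsim
Title: Desk-Scale Spiking-Network Simulation of the Cerebellar Microcircuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Clock-driven simulation of a biophysically constrained cerebellar
    microcircuit (glomeruli, granule, Golgi, stellate, basket, Purkinje and
    deep-nucleus cells) with conductance-based leaky integrate-and-fire
    dynamics solved by exact integration with sub-cycling. Two arithmetic
    back-ends are provided: a double-precision reference and an emulated
    s16.15 fixed-point mode with 16-bit power-of-two-scaled synaptic weights,
    including a weight-representability analysis. A synthetic connectivity
    generator reproduces the circuit's published synapse counts and fan-ins,
    a stimulus module implements the mossy-fibre burst protocol in Poisson
    and periodic encodings, an analysis module computes windowed firing
    rates, excited/inhibited classification, ISI/CV, binned spike-train
    correlations and PSTHs, and a communication-profiling module counts
    multicast packet load per processing core under alternative
    neuron-to-core partitioning strategies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
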