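Package: synchrate
Title: Temporal and Rate Coding in a Conductance-Based Model Auditory Cortical Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an auditory cortical neuron as a leaky integrate-and-fire
    unit driven by jittered alpha-function excitatory and inhibitory conductances,
    and analyzes its spike trains with the standard phase-locking and rate-coding
    statistics (vector strength, Rayleigh statistic, discharge rate ratio, minimum
    latency, onset/sustained ratio). Acoustic pulse trains and pure tones are
    rendered into conductance traces; feedforward inhibition is controlled by
    three parameters (I-E delay, I/E ratio, excitatory strength). Neurons are
    classified as synchronized, non-synchronized, or mixed, and parameter-grid
    sweeps map how the coding regime depends on the balance and timing of
    inhibition, including spontaneous-rate noise models, an NMDA kernel variant,
    and population-level comparisons.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
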