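Package: ictalnet
Title: Neuron-Astrocyte Network Simulation of Focal Ictal Discharge Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates focal seizure-like ictal discharge (ID) generation in a
    two-dimensional network of Izhikevich spiking neurons with conductance-based
    AMPA, NMDA, GABA-A and GABA-B synapses, slow activity-dependent excitability
    adaptation that terminates discharges, and an astrocyte sheet whose
    calcium-driven, thresholded glutamate (or GABA) release feeds back onto
    neurons. Includes the repeated focal depolarizing-pulse stimulation
    protocol, Monte-Carlo variant sweeps (astrocytes on/off, regional astrocyte
    blockade, inhibition strength, inhibitory gliotransmission), and outcome
    analytics: ID detection and threshold, duration, postictal refractoriness,
    propagation delay, excitation/inhibition balance traces, rate spectrograms
    and Poisson threshold statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
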