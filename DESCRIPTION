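Package: meakit
Title: High-Density Microelectrode Array Spike-Train Analysis and
    Excitatory/Inhibitory Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-density microelectrode array (HD-MEA)
    recordings of neuronal cultures with varying excitatory/inhibitory (E/I)
    composition: per-channel firing and burst metrics, array-wide network-burst
    detection with center-of-activity trajectories, functional-connectivity
    graphs from lagged cross-correlation, electrical-stimulation evoked-response
    and dispersion analysis, and an Izhikevich spiking-network simulator with
    spike-timing-dependent plasticity for E/I-ratio sweeps scored by the
    instantaneous network firing (INF) metric. Includes a synthetic-recording
    generator with planted ground truth so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
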