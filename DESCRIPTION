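Package: spikeflow
Title: Streaming Fixed-Point Spike Detection for Multi-Channel
    Extracellular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale emulation of a real-time extracellular spike
    detection datapath: a framed serial multi-channel stream is decoded by
    a Moore state machine, each channel is highpass-filtered by a
    fixed-point Direct-Form-II second-order Butterworth section, spikes
    are detected by a three-sample negative-peak threshold rule with
    per-channel refractory counters, and the filtered stream plus spike
    flags is re-encoded. Includes a synthetic recording generator with
    ground truth, an offline batch reference implementing the identical
    automaton, latency and clock-cycle budget models, and a validation
    protocol comparing streaming and offline spike counts per channel via
    percentage accuracy and percentage error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
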