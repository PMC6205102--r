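Package: phasenet
Title: Phase-Synchronization Network Dynamics of Multichannel
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds dynamic functional brain networks from multichannel
    electrophysiological recordings (ECoG and similar) by computing mean
    phase coherence between Hilbert-transform instantaneous phases in
    sliding windows. Reduces the resulting connectivity matrices to
    weighted node degrees and a whole-network mean phase synchronization
    series, identifies recurring network states by agglomerative Ward
    clustering of degree vectors with automatic selection of the number
    of states, and tracks state-change rates across preseizure, seizure,
    and postseizure periods. Group-level differences across periods are
    assessed with the Friedman test and Dunn's post hoc pairwise
    comparisons. Includes a coupled phase-oscillator simulator that
    generates seizure-like recordings with planted coupling schedules
    and known network states, so the whole pipeline can be validated
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
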