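Package: chipause
Title: Conductance-Based Model and Pause Metrics for Striatal Cholinergic
    Interneurons
Version: 0.1.0
Authors@R:
    person("Striatal", "Dynamics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-compartment conductance-based model of a striatal
    cholinergic interneuron (ChI) combining a passive leak, a fast
    inactivating A-type potassium current (I_A) and a slow non-inactivating
    delayed-rectifier potassium current (I_Kr, Kv7-like), with an optional
    dopamine D2-receptor hyperpolarizing current.  Includes current-clamp
    and voltage-clamp protocol simulation, stimulus waveform builders
    (sine, trapezoid, D2 shapes), spike detection, peri-event rate
    histograms with moving-average pause/rebound quantification, membrane
    potential undershoot statistics, first-harmonic phase-lag analysis,
    unit classification rules, and a seeded generator of synthetic
    in-vivo-like recordings (slow-wave inverted-LFP plus phase-coupled
    ChI/SPN spike trains) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
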