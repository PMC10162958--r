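Package: assrtools
Title: Simulation and Analysis of Auditory Evoked Potentials and 40 Hz
    Steady-State Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for murine auditory electrophysiology studies of
    excitation/inhibition balance: stimulus protocol and cross-over design
    construction (double-click evoked-potential and 40 Hz click-train
    steady-state paradigms), a synthetic session generator producing
    continuous EEG/LFP traces and single-unit spike trains under
    pharmacological (NMDA-antagonist and mGluR2/3-agonist) and optogenetic
    (parvalbumin-interneuron silencing) condition presets, ERP epoching with
    n1 amplitude and sensory-gating metrics, Morlet wavelet time-frequency
    decomposition with inter-trial coherence and evoked/total band power
    split into initial and maintenance response phases, peristimulus time
    histogram and firing-rate metrics for sorted units, and within-subject
    least-squares-means contrasts plus two-way optogenetics-by-drug
    inference mirroring cross-over study reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    emmeans,
    ggplot2,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
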