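Package: pulsetrim
Title: Topology Optimization and Reduction of One-Dimensional Arterial
    Pulse-Wave Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pressure and flow pulse waves in networks of compliant
    arteries with an explicit MacCormack scheme, couples terminal branches to
    three-element and coronary Windkessel models, and reduces network topology
    by two methods: algebraic lumping of distal resistance and compliance, and
    per-site optimization of Windkessel parameters against baseline waveforms.
    A topology-optimization framework searches for the smallest network whose
    waveform error at user-chosen sites stays below a threshold. Includes
    stenosis pressure-loss elements, hyperaemia scenarios, clinical indices
    (iFR, FFR, pulse and augmentation pressure) and input-impedance spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
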