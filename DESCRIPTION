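Package: vbplast
Title: Voltage-Based Modelling of Synaptic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulation and fitting of a phenomenological voltage-based rule
    for long-term synaptic plasticity, in which the glutamate trace left by
    presynaptic spikes interacts with two low-pass-filtered versions of the
    local dendritic voltage, and ongoing potentiation transiently raises the
    depression threshold (an LTP-on-LTD 'veto').  Includes synthesis of
    dendritic voltage traces for standard induction protocols (voltage clamp,
    square pulses, spike-timing pairings with bursts and dendritic spikes),
    closed-form and fine-grid reference implementations, bounded multi-start
    least-squares parameter fitting, leave-one-out cross-validation,
    sensitivity analysis, veto ablation, and a small command-line interface
    for working with recorded voltage traces in delimited text format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    lhs,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
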