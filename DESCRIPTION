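Package: emmoa
Title: Evolutionary Multitasking Multiobjective EEG Channel Selection for Hybrid BCIs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage evolutionary-multitasking multiobjective optimization for
    selecting EEG channel subsets in hybrid brain-computer interfaces that combine
    motor imagery (MI) and steady-state visual evoked potentials (SSVEP). A single
    population with per-individual task labels simultaneously maximizes MI
    classification accuracy (CSP features with an RBF-SVM), SSVEP classification
    accuracy (canonical correlation against sinusoidal references), and channel
    parsimony. Stage one maintains capped Pareto archives per task via
    non-dominated sorting and crowding distance; stage two partitions channels
    into add/delete/invalid groups by single-bit toggle voting over the archives
    and applies a guided local search, yielding a final three-objective Pareto
    set. Includes a synthetic hybrid-EEG generator with planted informative
    channels so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
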