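Package: CircuitPlasticity
Title: Quantification of Developmental Cortical-Circuit Plasticity Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipelines for electrophysiological assays of
    critical-period cortical plasticity: single-unit ocular-dominance scoring
    (ocular dominance index, seven-category scheme, contralateral bias index),
    laser-scanning photostimulation (LSPS) synaptic input maps with laminar
    binning, intracellular excitability and miniature postsynaptic-current
    statistics, field-EPSP slope and theta-burst LTP scoring, and the group
    statistics used with such data. Includes seeded synthetic-data generators
    with ground-truth labels for every input modality, enabling parameter
    recovery and power studies without raw recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
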