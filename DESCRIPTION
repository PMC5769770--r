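Package: tadbound
Title: TAD Boundary Analysis for Hi-C and 4C-seq with In Silico Deletion Alleles
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse topologically associating domain (TAD)
    boundaries from chromosome-conformation data. Builds in silico mutant
    (deletion/insertion) chromosomes with exact coordinate liftover,
    processes mapped Hi-C pair records into masked, ICE-balanced binned
    contact matrices, subtracts matrices across conditions, calls domains
    and boundaries with a TopDom-style insulation diamond and a multi-window
    consensus rule, and quantifies 4C-seq viewpoint profiles (fragment
    smoothing, viewpoint-window normalization, inter-domain contact ratios,
    cumulative contact curves, Ward clustering). A ground-truthed synthetic
    two-TAD locus generator with tunable boundary permeability, power-law
    distance decay, per-bin coverage biases and Poisson counts makes every
    pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
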