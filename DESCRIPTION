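Package: cellsizer
Title: Cell Size Homeostasis from Differential Size-Scaling of Cell-Cycle Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a whole-cell model of gene expression with
    limiting RNA polymerases and ribosomes, coupled to cell division rules based
    on the concentration ratio of cell-cycle activators (superlinear size
    scaling, weak promoters) to inhibitors (sublinear scaling, strong
    promoters). Provides self-consistent free-polymerase and free-ribosome
    solvers, calibration of transcription initiation rates to a target genome
    capacity and growth rate, event-driven single-lineage simulation with
    deterministic, stochastic, hazard-based, multi-regulator, gene-replication
    and asymmetric-division variants, a closed-form steady-state theory (birth
    volume, critical division thresholds, oscillation amplitude, stochastic
    birth-size moments, robustness condition), and lineage statistics (sizer
    correlations, equal-count binned regression, mutant panel comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
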