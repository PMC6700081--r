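Package: qsburst
Title: Individual-Based Simulation of Quorum-Sensing Induction Bursts in
    Growing Bacterial Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lattice-free, individual-based Monte Carlo simulator of early
    biofilm formation by quorum sensing. Cells in a growing two-dimensional
    colony emit a screened diffusive autoinducer field (steady-state modified
    Bessel K0 profile), perceive the superposed field of the whole colony, and
    switch irreversibly to an induced high-production state once the perceived
    concentration crosses a threshold, triggering cascades ("bursts") that can
    induce entire clusters within one division step. Includes both
    daughter-placement scenarios (fixed displacement distance and Gaussian
    spread), Poisson-disk, lattice and single-seed initial conditions, lineage
    tracking, and an ensemble-statistics layer: mean first-induction time,
    induction-time order parameters, burst detection, family and cluster
    metrics, static-configuration concentration ensembles, and the relative
    burst-size phase transition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
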