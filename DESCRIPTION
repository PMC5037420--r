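Package: cnmotility
Title: Cell-Nucleus Correlation Analysis of Single-Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies mesenchymal-like cell motility from paired cell and
    nucleus centroid trajectories. Per-interval displacements of the cell
    centroid (CCD) and the projection of the nucleus centroid displacement
    onto the CCD direction (NCD//) classify subcellular activity into
    angular regions (detachment, mixed, protrusion/retraction, large-angle
    side protrusion), rendered as time-ordered barcodes. The Cell Migration
    Potential Index (CMPI) summarises motility from Region I/II occupancy;
    a Monte-Carlo filter against an empirical fixed-cell noise density
    reassigns likely positioning noise to a stationary mode. Persistent
    random walk (Fuerth) fits of mean-squared displacement provide an
    independent motility benchmark, and simulators for event-scripted
    kinematics, exact Ornstein-Uhlenbeck persistent random walks and
    fixed-cell jitter support calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
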