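Package: prenuc
Title: Prenucleation Cluster Sizing, Growth Kinetics and Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for prenucleation molecular clustering of a
    drug-like solute in organic solvents. Sizes clusters from photon-correlation
    (dynamic light scattering) correlograms by second-order cumulant analysis
    and the Stokes-Einstein relation; quantifies cluster occupancy (number of
    solute molecules per cluster) and its growth rate from solvodynamic-diameter
    time series; diagnoses diffusion- versus interface-transfer-limited growth;
    computes classical-nucleation-theory driving forces and critical nucleus
    diameters for comparison with measured cluster sizes; and provides
    standalone periodic-box trajectory analyses (distance-cutoff clustering,
    radial distribution functions, hydrogen-bond detection and lifetimes,
    ring-stacking free-energy landscapes, pairwise nonbonded energies).
    Includes seeded synthetic-data generators with embedded ground truth for
    every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
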