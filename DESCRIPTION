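Package: scaffoldsim
Title: Hybrid Cellular-Automaton Simulation of Cell Populations in 3D Scaffolds
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of virtual cells cultured in three-dimensional
    polymeric scaffolds with a hybrid discrete/continuous cellular automaton.
    Cells on a cubic voxel lattice proliferate, migrate, quiesce, die and degrade
    according to a user-programmable probabilistic rule grammar, while glucose and
    oxygen diffuse through the scaffold by Fick's second law and proliferating
    cells stiffen their local extracellular matrix (Young's modulus remodeling).
    Includes an in-vitro-to-in-silico seeding scale factor, periodic media
    changes, an analysis layer (cell-density time courses, mean absolute
    percentage error validation, Manhattan-distance radial profiles, stiffness
    dispersion statistics, Kruskal-Wallis comparisons) and variance-based global
    sensitivity analysis (Saltelli sampling, first-order and total Sobol indices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
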