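Package: cylgel
Title: Coarse-Grained Simulation of Swelling and Collapse of Charged
    Cylindrical Microgels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds diamond-lattice cylindrical polyelectrolyte microgel
    networks, runs coarse-grained Langevin (Brownian) dynamics with a
    bead-spring force field (truncated Lennard-Jones, FENE bonds, Coulomb
    electrostatics at fixed Bjerrum length) in the NVT ensemble, sweeps
    solvent quality through the monomer attraction parameter, and measures
    the full set of shape and charge observables: contour length, slab
    thickness, gyration-tensor aspect ratio and asphericity, counterion
    localization, net-charge fraction, and cylindrical radial
    volume-fraction profiles. Includes closed-form synthetic-conformation
    fixtures, LAMMPS data/dump and XYZ interchange, and a reproducible
    sweep pipeline with tidy tabular results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
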