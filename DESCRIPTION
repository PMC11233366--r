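Package: vesicond
Title: Synapsin-Driven Vesicle Condensation: Langevin Simulation and
    Membrane Adhesion Energetics
Version: 0.1.0
Authors@R:
    person("Vesicond", "Developers", email = "vesicond@example.org",
           role = c("aut", "cre"))
Description: Tools for studying synapsin-induced condensation of lipid
    vesicles as a model of synaptic-vesicle pool formation. Provides a 2D
    coarse-grained Langevin simulator of vesicles decorated with tethered
    synapsin linkers (mono-domain single-bead and bi-domain rigid-dimer
    models), cluster detection via synapsin proximity and union-find,
    growth-curve and phase-diagram analysis of condensate coarsening and
    saturation, a spherical-cap membrane-adhesion energetics model that
    converts measured vesicle contact angles into adhesion energies per
    unit area, and seeded synthetic-data generators (truncated-normal and
    lognormal vesicle radius distributions with maximum-likelihood
    lognormal fitting).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
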