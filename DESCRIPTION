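Package: campath
Title: Minimum Free Energy Paths and Ion Permeation Analysis for
    Calcium Channel Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-ion permeation through narrow ion
    channels such as CaV1. Implements a basin/coarse-grained minimum free
    energy path (MFEP) search on gridded free-energy surfaces with
    exp(E/RT) resistance costs, reads and writes PLUMED-style grid files,
    counts permeation events and computes electronic-continuum-correction
    (ECC) corrected single-channel conductances, estimates selectivity
    ratios and Arrhenius rate ratios, analyses selectivity-filter binding
    sites, occupancy states and transition rates, applies ECC charge
    scaling to molecular topology files, and ships synthetic generators
    (toy landscapes, a well-tempered metadynamics toy sampler, a kinetic
    Monte Carlo knock-on simulator, and a multi-ion Langevin integrator)
    so the whole pipeline can be exercised without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
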