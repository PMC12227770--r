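Package: gcncmc
Title: Grand Canonical Nonequilibrium Candidate Monte Carlo for Toy Molecular Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation engine and analysis toolkit for grand canonical
    nonequilibrium candidate Monte Carlo (GCNCMC) sampling of molecule
    insertion and deletion. Provides soft-core alchemical switching with
    staged Lennard-Jones/electrostatic lambda schedules, Langevin (BAOAB)
    dynamics on self-contained toy particle systems, spherical and whole-box
    GCMC regions with the Adams-value acceptance tests, Widom test-particle
    estimation of excess chemical potentials, titration of the Adams value to
    dissociation constants and standard binding free energies via logistic
    fits, occupancy-grid mapping of binding sites, and binding-mode
    population analysis by dihedral binning and pairwise-RMSD clustering.
    Deterministic fixture generators with analytic grand-canonical ground
    truths support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
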