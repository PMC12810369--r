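Package: ionlayer
Title: Divalent Cation Binding at Carboxylate-Terminated Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying alkaline-earth metal ion adsorption at the
    aqueous interface of an anionic carboxylate-terminated self-assembled
    monolayer. Provides a reduced Brownian-dynamics simulator of ions above an
    idealized deprotonated thiol lattice (12-6 Lennard-Jones plus Coulomb
    nonbonded potential, optional electronic-continuum-correction charge
    scaling), readers and writers for GRO/XYZ coordinates and XVG-style force
    series, radial-distribution-function analysis with binding-motif
    classification (bidentate, monodentate, solvent-shared), and three
    binding-strength estimators: adhesion forces from constant-rate pulls,
    potential-of-mean-force free energies via the weighted histogram analysis
    method with Bayesian bootstrap errors, and Langmuir-isotherm standard
    binding free energies. Includes conversions from atomic force microscopy
    adhesion forces to binding free energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
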