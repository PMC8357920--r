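Package: neqnet
Title: Charge- and Spin-Conditioned Neural Interatomic Potentials with
    Neural Spin-Charge Equilibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Symmetry-function neural interatomic potentials that accept a
    total molecular charge and spin multiplicity as input and return total
    energies together with per-atom, per-spin-channel partial charges.  The
    central component is a Neural Spin-charge Equilibration (NSE) output unit
    that redistributes raw predicted atomic spin charges so that each spin
    channel sums exactly to the requested molecular spin charge.  The package
    also derives conceptual-DFT reactivity descriptors (vertical ionization
    potential and electron affinity, electronegativity, chemical hardness,
    electrophilicity, condensed Fukui and philicity indexes) from three-state
    predictions at fixed geometry, extracts per-atom site descriptors for
    electrophilic aromatic substitution modelling, and ships a deterministic
    electronegativity-equalization physics surrogate that generates labelled
    toy datasets (energies plus spin-resolved charges across neighbouring
    charge states) so the whole system trains and validates at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
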