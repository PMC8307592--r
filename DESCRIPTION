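Package: detbelt
Title: Detergent Belt Modelling Around Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the amphipathic solvent belt that wraps the transmembrane
    surface of a detergent-solubilized membrane protein as a hollow cylinder.
    Given a membrane-oriented PDB structure (z axis normal to the membrane,
    origin at the membrane centre) and a count of detergent monomers, the belt
    height is taken from the membrane thickness, the inner radius from the
    solvent-exposed transmembrane atom shell (Shrake-Rupley accessible surface
    area, radial kernel-density mode detection), and the outer radius from
    conservation of the total detergent volume. Ships a curated detergent and
    lipid database with an additive monomer-volume estimator, detergent-mixture
    stacking, metrics export, PyMOL rendering scripts, pseudo-atom belt shells,
    a synthetic fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
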