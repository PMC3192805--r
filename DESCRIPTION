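Package: potdecomp
Title: Decomposition of Residue Contact Potentials into Hydrophobic and
    Hydrogen-Bonding Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing 20x20 residue-residue contact free-energy
    matrices (knowledge-based statistical potentials such as the
    Miyazawa-Jernigan matrix and beta-strand pairing potentials). Fits the
    matrices as a linear combination of binary hydrophobic-polar (HP) and
    backbone hydrogen-bonding (HB) basis matrices plus residue-specific
    one-body terms under class-wise zero-sum gauge constraints, and provides
    the surrounding analyses: class-resolved Gaussian summaries of contact
    free-energy distributions, solvation correction of per-residue
    secondary-structure scales, proline-contact sensitivity scaling,
    hydropathy reclassification batteries, disulfide handling, a seeded
    synthetic-matrix generator, and a command-line interface. Readers and
    writers for square, lower-triangle and AAindex-style matrix files are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
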