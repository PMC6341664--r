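Package: hptkit
Title: Conservation, Binding and Structural Analysis of Histidine
    Phosphotransfer Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying histidine phosphotransfer (HPt) proteins such
    as yeast Ypd1: anchor-relative residue-conservation censuses on family
    alignments (redundancy filtering, phospho-histidine anchor detection,
    H+k composition tables, sequence-logo information content), dissociation
    constant estimation from fluorescence titrations via the ligand-depletion
    quadratic binding isotherm, percent-of-wild-type quantification of
    phosphotransfer gel bands, and structural comparison of mutant and
    wild-type coordinates (Kabsch superposition, regional RMSD, van der Waals
    clash scanning). Seeded synthetic-data generators emulate each input so
    every analysis stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
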