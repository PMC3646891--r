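Package: lipidenum
Title: Rule-Based Enumeration of Theoretical Glycerolipids and
    Glycerophospholipids with an MS1 Precursor Search Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates the theoretical space of glycerolipids and
    glycerophospholipids from a small set of chemical rules governing
    fatty-chain composition (carbon range, odd-chain allowance, double-bond
    spacing), organises the records in the four-level identification
    hierarchy used by mass-spectrometry lipidomics (Species, Fatty Acid
    Scan Species, Sub Species, Isomer), formats and parses shorthand lipid
    nomenclature, computes molecular formulas and neutral monoisotopic
    masses by condensation arithmetic from head-group and chain building
    blocks, counts records at every hierarchy level combinatorially
    without enumeration, and annotates MS1 precursor-ion mass lists
    against the species-level space with configurable adducts, tolerance
    and class filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
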