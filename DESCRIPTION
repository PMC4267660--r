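Package: fretends
Title: Single-Molecule FRET Analysis of RNA 5'-3' End-to-End Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Burst analysis of single-molecule Fluorescence Resonance Energy
    Transfer (smFRET) photon traces, with a seeded synthetic-data generator,
    double-stranded DNA ruler calibration of the effective Forster radius,
    inversion of FRET efficiencies to inter-dye distances with propagated
    uncertainty, linker correction and length-trend regression, and
    rigid-rod / worm-like-chain conversion of end-to-end distances to
    exterior-loop contour lengths, including shot-noise and chain-fluctuation
    histogram-width analysis. Designed for studies of the 5'-3' end-to-end
    separation of long single-stranded RNA molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
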