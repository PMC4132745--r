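Package: smtether
Title: Single-Molecule Analysis of Protein-Induced DNA Compaction, Bridging and Looping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of single-molecule DNA-protein mechanics:
    extensible worm-like-chain (WLC) fitting of optical-tweezers force-extension
    curves, McGhee-von Hippel cooperative lattice-binding titration analysis of
    persistence length, contour length and overstretching force, detection and
    sizing of protein-stabilized DNA loop-rupture events, constant-force
    compaction kinetics, and AFM-trace analysis (2D WLC persistence length,
    protein-induced bend angles, loop and bridge statistics). Includes seeded
    synthetic-data generators for every input type so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
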