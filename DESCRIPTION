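Package: pciqc
Title: Postcolumn Infusion Quality Control for LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for using postcolumn infusion (PCI) of standards as a
    routine quality-control readout in LC-MS bioanalysis. Extracts
    matrix-effect profiles of continuously infused standards across whole
    chromatograms, detects ion-suppression and ion-enhancement regions
    against a reference injection, attributes them with diagnostic screens
    (phosphocholine fragment for phospholipids, 44 Da polymer ladders for
    polyethylene glycol), and monitors batch-level drift and
    column-buildup trends per injection order. Ships a seeded synthetic
    LC-MS run simulator (mzML in/out) so every step is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
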