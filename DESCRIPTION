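Package: esterkin
Title: Solvolysis Kinetics and QSPR Modelling of Corticosteroid Ester
    Prodrugs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for in vitro prodrug-activation studies of
    fluocinolone acetonide C-21 esters. Fits pseudo-first-order solvolytic
    rate constants from HPLC calibration curves and peak-area time courses,
    assembles quantum-chemical bond-polarity descriptors (Mulliken charge
    differences times bond length) across several theory and solvation
    levels, screens descriptors against rate constants by Pearson
    correlation, fits the single-descriptor QSPR line with full ordinary
    least-squares statistics, and links rate constant and lipophilicity to
    anti-inflammatory activity by multiple regression. Ships the published
    descriptor table as a checksummed plain-text fixture with a
    machine-readable annotation list, plus a synthetic-data generator for
    calibration standards, solvolysis time courses and activity data so the
    whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
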