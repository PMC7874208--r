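Package: vsrquant
Title: Quantification of the Vestibulospinal Reflex in Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the vestibulospinal reflex (VSR) assay in
    head-fixed zebrafish larvae under sinusoidal yaw stimulation. Segments
    tail-angle recordings into black-frame-delimited stimulus cycles, computes
    artifact-subtracted per-cycle activity metrics (maximum tail angle of the
    difference signal, normalized integral, percentage of time above threshold),
    derives trial-level fatigue and recovery statistics (half-time of decline,
    pause durations, minimal recovery interval), and compares genotype groups
    per cycle with Benjamini-Hochberg correction. Includes a midline tracker
    recovering tail angles from rendered frame sequences and a seeded synthetic
    generator for wild-type, mechanotransduction-null, and depletion/recovery
    phenotypes.
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
    nortest,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
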