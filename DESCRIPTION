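Package: maldiscreen
Title: Suspect Screening of Plastic Additives in AP-MALDI-qTOF Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Suspect screening of plastic additives (flame retardants,
    plasticizers, antioxidants, UV stabilizers) in centroided AP-MALDI-qTOF
    mass spectra acquired on 48-well target plates. Expands a compound
    database into adduct and in-source fragment ion species, recalibrates
    well spectra against perfluoroalkyl sulfonic acid (PFSA) reference ions,
    matches species by exact mass with an isotope-pattern goodness-of-fit
    score, applies blank-based detection thresholds and triplicate-consensus
    validation, and reports detections at confidence level 4 (exact mass and
    isotope pattern). Includes exact isotope-pattern computation from a
    bundled isotope table, spot-to-spot and extract-to-extract relative
    standard deviation statistics, and a seeded synthetic plate generator
    producing spectra, manifests and ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    mzR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
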