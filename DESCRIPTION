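Package: qamsfp
Title: HPLC Fingerprinting and Single-Marker Quantitation for Herbal Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality evaluation toolkit for multi-herb preparations analysed
    by dual-wavelength HPLC. Builds chromatographic fingerprints from
    cross-batch common peaks (solvent-front shearing, area screening,
    retention-time matching), scores batches against a median-method
    reference fingerprint by cosine similarity, screens key components with
    correlation-matrix PCA and NIPALS PLS-DA variable importance (VIP), and
    quantifies marker analytes by the single-marker method (QAMS) with
    relative correction factors, validated against external-standard
    calibration, spike recovery, and relative-error comparison. Includes a
    synthetic chromatogram generator with known ground truth so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
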