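Package: mcxray
Title: Quantitative X-Ray Microanalysis of Tissue Microcalcifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for scanning X-ray studies of breast-tissue
    microcalcifications across three modalities. Provides thickness-constrained
    X-ray fluorescence (XRF) quantification of matrix-referenced elemental mass
    fractions from multi-energy raster scans, Ca K-edge XANES normalization and
    non-negative linear-combination fitting against a mineral reference library,
    and WAXS profile classification plus whole-pattern refinement of
    hydroxyapatite and whitlockite cell parameters and anisotropic crystalline
    domain sizes. A synthetic phantom generator renders co-registered
    transmission maps, XRF spectrum cubes, XANES point spectra and WAXS profiles
    from one ground-truth scene description, emulating benign, in-situ and
    invasive carcinoma deposit morphologies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
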