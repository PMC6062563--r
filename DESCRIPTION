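Package: msforge
Title: Direct-Infusion Mass-Spectrometry Fingerprinting for Manuscript Authentication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating handwritten documents from direct-infusion
    nanospray mass spectra of ink and paper extracts. Implements per-file
    normalization to total usable signal, greedy ppm-tolerance peak alignment
    into cross-file peaksets, solvent-blank-aware feature screening with
    Benjamini-Hochberg corrected differential statistics, document-grouped
    cross-validated hard-margin RBF kernel classification with pooled ROC/AUC,
    molecular-formula adduct annotation of diagnostic ions, and ink-signature
    marker detection. Includes a synthetic corpus generator emulating a
    two-author manuscript study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
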