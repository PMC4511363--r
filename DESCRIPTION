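Package: qconquant
Title: Absolute Protein Quantification by QconCAT Isotope Dilution Mass
    Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for absolute quantification of low-abundance serum
    proteins by isotope dilution mass spectrometry with concatamerized
    (QconCAT) 15N-labelled fingerprint peptides. Provides in-silico
    tryptic digestion and peptide mass bookkeeping for light and heavy
    label states, fingerprint-peptide candidate evaluation with a
    cleavage-context uniqueness screen against a background proteome,
    peptide-mass-fingerprint identification with sequence coverage,
    extracted-ion-chromatogram peak integration and light/heavy ratio
    quantification with serum-concentration back-calculation, the
    summary statistics used in spike-in calibration and cohort
    comparison, and a synthetic LC-MS run generator so the full
    pipeline is testable without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
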