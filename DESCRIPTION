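Package: residuescreen
Title: Targeted LC-HRMS Quantification and Validation of Veterinary Drug
    Residues in Fish
Version: 0.1.0
Authors@R:
    person("Residue", "Screen Developers", email = "residuescreen@example.org",
           role = c("aut", "cre"))
Description: Tools for targeted quantification of sulfonamide and trimethoprim
    residues in fish muscle by high-resolution LC-MS: elemental-formula parsing
    and monoisotopic mass arithmetic, accurate-mass and retention-time identity
    confirmation with identification-point scoring, matrix-matched least-squares
    calibration, method-validation statistics (matrix effect, recovery, intraday
    and interday precision, decision limit CCalpha, detection capability CCbeta,
    LOD/LOQ), and maximum-residue-limit compliance screening including the
    summed-sulfonamide rule. A synthetic-data module simulates integrated peak
    tables and chromatograms with the statistical structure of a full validation
    campaign, providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
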