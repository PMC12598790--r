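Package: dnabind
Title: Drug-DNA Interaction Analysis from Titration, Melting, Viscosity,
    and Voltammetry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates small-molecule/double-stranded-DNA binding constants
    from UV-vis titrations (Benesi-Hildebrand), fluorescence quenching
    (Stern-Volmer and double-logarithmic analyses, dye-displacement
    comparison), and differential pulse voltammetry, together with van't
    Hoff thermodynamics, DNA melting-temperature shifts, relative-viscosity
    and Herschel-Bulkley rheology analyses, and a validated voltammetric
    quantification workflow (calibration, LOD/LOQ, repeatability, tablet
    assay, recovery). A rule-based classifier aggregates the per-technique
    evidence into a binding-mode call (minor groove, intercalation,
    electrostatic, or indeterminate). Includes a synthetic-data generator
    that emulates every supported signal type with known ground-truth
    parameters so each estimator is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
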