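Package: icescreen
Title: Hybrid Targeted and Untargeted UHPLC-HRMS Screening of Organic
    Tracers in Ice and Snow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational workflow for hybrid targeted/untargeted
    liquid-chromatography high-resolution mass-spectrometry screening of
    wildfire and water-soluble organic tracers in ice-core and snow
    samples. Provides molecular-formula parsing and monoisotopic
    deprotonated-ion mass arithmetic, exhaustive formula assignment for
    measured features within a ppm tolerance, Kendrick mass defect
    computation and CH2-homologue series mining, Van Krevelen and carbon
    oxidation state (Kroll) classification, spectral-similarity scoring
    with Schymanski-style identification confidence levels, internal
    standard calibration with limit-of-detection, matrix-effect and
    recovery validation statistics, frozen-versus-unfrozen storage
    comparisons, and a seeded synthetic-data generator that emulates
    every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
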