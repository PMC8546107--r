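Package: retimet
Title: Retinal Oxygen Metabolism and Haemodynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for retinal oxygen metabolism and
    haemodynamics in three-group ocular cohort studies. Converts dual-beam
    Doppler OCT phase measurements into absolute blood velocities,
    per-vessel volumetric flow and total retinal blood flow; folds
    reflectometry-derived vessel oxygen saturations into an oxygen-content
    and retinal oxygen-extraction model; computes Knudtson central retinal
    artery and vein equivalents; quantifies capillary and large-vessel
    density on en-face OCT angiography images with Hessian-based vessel
    separation in an annular peripapillary region; summarises structural
    OCT layers; and runs the planned-contrast ANOVA group comparison.
    Includes a synthetic-cohort generator with recorded ground truth for
    every derived quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
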