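Package: braggdna
Title: DNA Damage Complexity, Microdosimetry and Cell Survival Along a
    Proton Bragg Curve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale pipeline linking position in a proton Bragg curve to
    DNA damage complexity and clonogenic survival. Provides a seeded
    parametric generator of proton-track DNA lesion sets, clustering-based
    classification of damage sites into single-strand breaks, double-strand
    breaks (DSB) and complex DSB classes (DSB+, DSB++) with direct/indirect
    source typing, lineal-energy spectra and dose-averaged mean lineal energy
    statistics, linear-quadratic fitting of clonogenic survival with
    D37/D10 interpolation, biexponential fitting of 53BP1 focus-resolution
    kinetics with half-life extraction, and quantification of two-channel
    nucleus images (DAPI segmentation, threshold-based focus detection,
    moment-based ellipse fitting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
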