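Package: mammodef
Title: Prone-to-Supine Breast Deformation Modeling and MR Density Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating ultrasound shear-wave breast stiffness to
    MR-measured breast density through biomechanical simulation. Generates
    synthetic prone breast MR phantoms and elastography cohorts, segments
    breast and fibroglandular tissue with bias-field correction and fuzzy
    C-means clustering, builds labeled tetrahedral meshes, deforms them from
    the prone to the supine configuration with a total Lagrangian explicit
    dynamics finite-element solver using a neo-Hookean material model
    (zero-gravity estimation followed by inverse-gravity loading stopped at a
    target breast depth), measures whole-breast and local percent density in
    an ultrasound-equivalent region of interest, and reproduces the cohort
    correlation and reproducibility analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
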