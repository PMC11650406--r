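Package: pfafield
Title: Waveform-Independent Field Modelling of Pulsed-Field Ablation Catheters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale electro-quasistatic comparison of pulsed-field ablation
    (PFA) catheter designs. Generates labeled voxel phantoms of a left pulmonary
    vein antrum (blood pool, 2.5 mm myocardial wall, background tissue, return
    patch), rasterizes six parametric catheter electrode sets with their vectoring
    schemes, solves the nonlinear volume-conductor problem
    div(sigma(|grad phi|) grad phi) = 0 with a finite-volume Picard/PCG solver
    driven to a prescribed per-vector current, and computes three outcome
    metrics: percent of delivered power reaching the target, per-vector current
    for 90 percent transmural electroporation (>600 V/cm), and electrode current
    density. All computations are instantaneous static solves, so designs are
    compared without knowledge of proprietary pulse waveforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
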