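Package: laminarbold
Title: Calibrated-BOLD Analysis of Laminar fMRI Gas Challenges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hyperoxia- and hypercapnia-calibrated BOLD analysis across
    cortical depth. Implements the oxygen-transport chain for venous
    deoxyhemoglobin under hyperoxia, M-value estimation, the Davis forward
    model with Grubb flow-volume coupling, and its inversion to venous
    cerebral blood volume change; a general linear model stage with binary
    gas-condition regressors, physiological nuisance regressors and
    Holm-Bonferroni voxel selection; equivolumetric-layer depth binning and
    depth-profile aggregation for gradient-echo and spin-echo contrasts; and
    a synthetic laminar fMRI generator that drives every stage from known
    per-voxel ground truth so the full pipeline is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
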