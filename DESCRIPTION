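Package: gdmrt
Title: Geometry Deformation Margins for Marker-Tracked Stereotactic Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Target-definition workflow for marker-tracked stereotactic
    radiotherapy of moving targets, such as stereotactic arrhythmia
    radioablation with an implanted ICD lead tip as the tracked surrogate.
    Implements the triple rigid-registration chain (6-DOF spine alignment,
    translation-only marker alignment, translation-only alignment to an
    in-organ reference structure) that measures per-breathing-phase
    marker-target geometry changes, builds the anisotropic geometry
    deformation margin (GDM) and its subvolume-union alternative to expand
    a clinical target volume into internal and planning target volumes, and
    quantifies volume agreement and observer variability with the DICE
    coefficient and average Hausdorff distance. Includes a synthetic
    respiratory thorax phantom with exported ground truth for validating
    every stage of the chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
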