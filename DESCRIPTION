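Package: TwoStepIMRT
Title: Geometry-Driven Step-and-Shoot IMRT Planning with Single-Segment Beams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for fast step-and-shoot intensity-modulated radiotherapy
    (IMRT) planning built on a geometrical analysis of the planning target
    volume (PTV) and organ-at-risk (OAR) topology. Constructs conformal (S0),
    OAR-blocking (S1) and narrow rim-saturating (S2) multi-leaf collimator
    apertures from beam's-eye-view projections, assembles single-segment-per-
    beam plans of alternating segment order, fine-tunes segment weights and
    apertures against weighted quadratic dose-volume objectives, and scores
    plans by composite objective value and dose-shortfall metrics. Includes a
    linac delivery-time machine model with presets for older and newer
    accelerators, synthetic voxel phantoms (horseshoe target around a central
    OAR, nested boost targets, tangent-field geometry), and an end-to-end
    experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), RNifti, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
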