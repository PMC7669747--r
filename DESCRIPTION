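Package: isptrack
Title: Trajectory and Image Analysis for Interferometric Single-Particle
    Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for high-speed interferometric scattering
    (iSCAT) single-particle tracking of membrane proteins: rolling-window
    time-averaged mean square displacement with localization-error
    correction, directional correlation statistics, accumulated total
    occupancy maps with extended-residency patch detection, directed-
    transport step extraction, and sphere fitting of bowl-confined 3D
    trajectories. Includes seeded generators for every mobility model the
    analyses target (Brownian, fractional Brownian, hop, corral, bowl,
    stepper, landing) and a phenomenological interferometric point-spread-
    function imaging module with radial-symmetry lateral localization and
    central-contrast axial calibration, so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
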