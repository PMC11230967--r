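Package: SurfNav
Title: Markerless Surface-Based Registration for Tracked Multimodal Camera Rigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for registering a preoperative magnetic-resonance head model to
    depth-camera data without fiducial markers, and for keeping that registration
    valid while a tracked camera rig moves. Implements rigid-transform and camera
    geometry (rational distortion model), saturated-marker detection and
    perspective-n-point calibration of the fixed transform between a tracked rigid
    body and the infrared camera's optical centre, inter-camera homography
    estimation, depth-bias curve correction, face extraction from depth frames,
    principal-component alignment and hidden point removal of the MR surface,
    RANSAC-initialised iterative-closest-point registration, pose-stream Kalman
    filtering, fiducial/target/relative registration error metrics, and a
    deterministic phantom simulator that stands in for the camera, tracker and
    phantom hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    EBImage,
    RNifti,
    minpack.lm,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'io-npy.R'
    'io-ply.R'
    'io.R'
    'geometry.R'
    'kalman.R'
    'mr.R'
    'depth.R'
    'registration.R'
    'evaluation.R'
    'sim.R'
    'cli.R'
    'homography.R'
    'tracking.R'
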