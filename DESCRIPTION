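Package: starstack
Title: Stack-of-Stars Golden-Angle MRI Simulation and Real-Time
    Compressed-Sensing Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating 3D real-time radial
    stack-of-stars MRI acquisitions of swallowing. Generates aligned and
    rotated (golden-angle and tiny-golden-angle) stack-of-stars spoke
    schedules, computes point-spread functions and their incoherence by
    adjoint gridding NUFFT, simulates multi-coil radial k-space from a
    dynamic digital swallowing phantom with coil noise and hardware
    imperfections, reconstructs image series by CG-SENSE and compressed
    sensing with locally-low-rank plus temporal total-variation
    regularisation (including a sliding-window mode and flat-field
    correction), and quantifies image quality (SSIM) and swallowing
    parameters (duration, bolus area and volume, laryngeal elevation,
    submental muscle contraction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
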