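Package: octa3d
Title: Depth-by-Depth Adversarial Enhancement of Volumetric OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to enhance volumetric optical coherence tomography
    angiography (OCTA) by applying a Pix2Pix-style generative adversarial
    network to C-scan slices depth-by-depth. Includes a synthetic vascular
    phantom generator, registration and averaging of repeated en face
    acquisitions into reference labels, synthesis of degraded training
    inputs from en face projections and avascular C-scan noise, a from-
    scratch U-shaped generator and convolutional discriminator with L1
    content plus adversarial losses trained by Adam, maximum-intensity and
    depth-encoded projections, and vascular quality metrics (contrast-to-
    noise ratio, vessel density, vessel diameter index, vessel continuity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
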