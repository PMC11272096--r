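Package: apunet
Title: Attention-Based Physical U-Net Enhancement of Diffuse Optical Tomography Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates frequency-domain diffuse optical tomography (DOT) measurements of
    breast-tissue phantoms with realistic degradation modes (optode coupling errors, tissue
    heterogeneity, shot noise, source artifacts), reconstructs absorption perturbation maps
    with a dual-mesh Tikhonov-regularized conjugate-gradient Born solver, and trains and
    evaluates an attention-based physically informed U-Net (APU-Net) that removes image
    artifacts and restores the lesion depth profile. Includes the contextual-transformer
    attention block, the weighted/perceptual/perturbation composite loss, depth-contrast and
    artifact-contrast image-quality metrics, and an attention-ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
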