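Package: blindspot
Title: Mask-Free Self-Supervised Blind Image Denoising with a J-Invariant Dilated Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for blind denoising of single-channel images without clean
    targets or masking schemes. Builds small convolutional denoisers that are
    J-invariant by construction (a donut-shaped first kernel whose center
    weight is structurally zero, followed by parallel stacks of dilated
    convolutions), trains them directly on noisy images with a plain or
    adaptive self-supervision loss (optionally with total-variation
    regularization or loss clipping), and verifies the invariance property
    both analytically (receptive-field offset sets) and empirically
    (perturbation and gradient probes). Includes simulators for Gaussian,
    speckle, salt-and-pepper and fused noise, a procedural clean-image
    generator, PSNR/SSIM quality metrics, eight-fold dihedral test-time
    averaging, and an end-to-end simulate/train/denoise/evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
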