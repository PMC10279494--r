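Package: pcfbsr
Title: Single-Image Super-Resolution of MR Slices with Parameter-Free
    Chunking Fusion Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-image super-resolution of 2-D magnetic
    resonance slices. Implements a residual convolutional network with
    PReLU activations, layer normalisation, a parameter-free chunking
    fusion block built on SimAM energy-based attention, and sub-pixel
    (PixelShuffle) reconstruction, trained with a composite loss
    (pixel L1 + perceptual + Laplacian edge terms) by Adam with Xavier
    initialisation. Includes the two standard low-resolution simulators
    (bicubic downsampling and k-space truncation), full-reference image
    quality metrics (RMSE, PSNR, SSIM), a synthetic phantom generator
    emulating gray-scale MR slices, paired patch extraction with
    augmentation, dataset splitting, PNG/TIFF/NIfTI image I/O, and a
    command-line interface covering the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    RNifti,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
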