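Package: ramanstain
Title: Virtual H&E Staining from Raman Hyperspectral Images via
    Cross-Modal Latent Alignment and Conditional Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesizing hematoxylin-eosin (H&E) style
    histology sub-images from label-free Raman hyperspectral tissue scans.
    Implements a cosine-similarity alignment network that classifies and
    cross-modally aligns Raman and H&E image patches through a shared bank
    of trainable seed vectors, a two-step top-K masking rule that turns
    Raman patch/target similarities into convex-combination conditioning
    vectors, and a conditional denoising-diffusion UNet that generates H&E
    sub-images under cross-attention conditioning. Includes physical-
    resolution tiling utilities, a convolutional autoencoder for
    pretraining the frozen H&E encoder, a synthetic co-registered
    phantom-data generator, region-majority diagnostic scoring, and a
    pipeline orchestrator. The neural-network machinery (reverse-mode
    automatic differentiation, convolution, normalization, attention,
    AdamW) is implemented in base R and verified against finite
    differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
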