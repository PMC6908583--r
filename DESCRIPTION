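Package: ganrecon
Title: Tissue Classification by Per-Class Edge-Conditioned GAN Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A modular, model-per-class framework for classifying histology
    image tiles. One conditional generative adversarial network (cGAN) is
    trained per tissue class to reconstruct H&E-like tiles from their
    channel-wise Canny edge maps; an unseen tile is classified by which class
    generator reconstructs it with the smallest error (MSE, or optionally
    SSIM/PSNR based dissimilarities). Includes a U-Net generator and
    convolutional discriminator implemented in base R, stereology grid
    sampling of tiles from annotated images, high-power-field classification
    by majority vote over randomly sampled windows, grouped k-fold
    evaluation with precision/sensitivity/F1 reporting, and a seeded
    synthetic-texture generator so the full pipeline is testable without
    external slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    Matrix
Suggests:
    tiff,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
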