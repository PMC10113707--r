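Package: lesionsynth
Title: Synthetic Liver Lesion Generation by Shape Modelling and Partial-Convolution Inpainting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic labelled lesions for augmenting medical image
    segmentation training sets. Lesion shapes are drawn from a point-distribution
    model (Procrustes-aligned boundary landmarks followed by principal component
    analysis) and placed on healthy tissue; lesion textures are painted into the
    masked region by a partial-convolution U-Net generator trained adversarially
    against a spectrally normalised Wasserstein critic with gradient penalty,
    reconstruction, perceptual and Gram-matrix texture losses. Realism of the
    synthetic lesions is scored by Kullback-Leibler divergence between gray-level
    co-occurrence matrix (GLCM) feature distributions of real and synthetic lesion
    regions, and a U-Net segmentation stage with combined cross-entropy and Dice
    loss quantifies the augmentation benefit. A seeded CT-like phantom generator
    makes the whole pipeline runnable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    RNifti,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
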