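Package: HahnFusion
Title: Multi-Modal Brain Image Fusion with Hahn Moments and Pulse-Coupled Neural Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end feature-level fusion framework for co-registered
    structural (MRI/CT-like) and functional (PET/SPECT-like) brain images.
    Convolutional layers extract multi-channel features from each modality;
    each feature map is partitioned into blocks whose activity is measured by
    the potential energy of their discrete orthogonal Hahn moments; a
    simplified pulse-coupled neural network (PCNN), with saliency-derived
    link strengths, arbitrates block-wise between sources; and convolutional
    layers reconstruct a three-channel fused image. The package includes a
    composite training loss (pixel cross-entropy, multi-scale structural
    similarity, total variation), a six-metric fusion-quality evaluation
    suite (Q_AB/F, SSIM, VIF, FMI, spatial frequency, cross entropy), a
    seeded generator of co-registered brain-like phantoms for fully offline
    testing, and tri-modal (CT + MRI + PET) fusion support.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, grDevices, utils, png, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, yaml, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils-filters.R'
    'HahnFusion-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'hahn.R'
    'pcnn.R'
    'blocks.R'
    'saliency.R'
    'fusion.R'
    'conv.R'
    'network.R'
    'loss.R'
    'train.R'
    'metrics.R'
    'phantom.R'
    'io.R'
    'pipeline.R'
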