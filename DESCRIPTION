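Package: musclesegkit
Title: Muscle MRI Segmentation with Shape-Model Data Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multi-label skeletal-muscle segmentation of lower-limb
    MR volumes: seeded synthetic phantom generation, per-muscle statistical
    shape models built from particle-based surface correspondence and PCA,
    nodal-grid deformable registration, label-preserving cohort augmentation
    that produces perfectly matched image/label pairs, four encoder-decoder
    segmentation networks (U-Net, UNet++ and feature-fusion variants with
    attention gates and CBAM), slice-wise training and 3D reassembly, and 3D
    evaluation metrics (Dice similarity, relative volume error, Hausdorff
    distance) with paired nonparametric model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, RNifti, jsonlite, stats, utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
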