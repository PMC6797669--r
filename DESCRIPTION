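Package: usreg
Title: Segmentation-Based Registration of Intraoperative Ultrasound Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compensates brain shift in image-guided neurosurgery by
    registering 3D intraoperative ultrasound volumes acquired at successive
    resection stages. Hyperechogenic structures (sulci, falx cerebri) are
    segmented with a 3D U-Net trained on image patches; the resulting masks
    drive a variational registration that combines a translation/rigid
    pre-alignment with a multilevel nonparametric elastic stage optimized
    by limited-memory BFGS. Ships a synthetic ultrasound phantom generator
    with known deformations, resection cavities and landmark
    correspondences, plus landmark-based target registration error
    evaluation, Dice/Jaccard overlap measures and capture-range estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
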