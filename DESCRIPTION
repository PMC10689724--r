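Package: msseg2d
Title: Multi-Branch 2D U-Net Segmentation of Multiple Sclerosis Lesions
    in Multi-Modal Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Slice-based segmentation of multiple sclerosis lesions from
    co-registered multi-modal brain MRI (FLAIR, T1w, T2w).  Volumes are
    sliced along the axial, coronal and sagittal planes, normalized and
    resized to 256x256; a three-branch 2D U-Net with one encoder per
    modality, multi-modal feature-fusion (MMFF) and multi-scale
    feature-upsampling (MSFU) blocks predicts per-slice lesion
    probabilities; the three restacked probability volumes are averaged
    and thresholded into a binary lesion mask.  Includes a compact
    reverse-mode CNN engine with Adam, a variance-window checkpoint
    selection rule, synthetic multi-modal phantoms for fully offline
    testing, and the voxel- and lesion-wise evaluation suite (DSC,
    Jaccard, PPV, TPR, LFPR, LTPR, volume difference, composite
    challenge score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
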