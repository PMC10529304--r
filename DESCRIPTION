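Package: nodeseg
Title: CT-Based Automatic Lymph Node Segmentation and PET
    Semi-Quantification for Intraoperative Specimen PET/CT
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic segmentation of lymph-nodal structures in
    high-resolution intraoperative PET/CT specimen images. Tissue classes
    (air, fat, node/soft tissue) are separated by one-dimensional k-means
    clustering of CT attenuation values; the nodal cluster is refined by
    geometric removal of the specimen case, binary erosion, hole-filling,
    slice-wise and volumetric small-feature filtering, and dilation. The
    resulting masks are resampled onto the PET grid by nearest-neighbour
    interpolation to compute SUVmax and target-to-background ratios per
    node. Includes a voxel-wise evaluation module (precision, recall, Dice,
    Jaccard, accuracy with micro/macro/weighted averaging) against a
    reference mask, and a synthetic specimen-phantom generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    oro.nifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
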