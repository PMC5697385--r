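Package: CornerDx
Title: Corner-Based Classification of Brain CT/MRI Slices via Multilayer
    Texture Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a corner-based pipeline for two-class (Normal vs
    Abnormal) classification of 2-D grayscale brain CT and MRI slices.
    Slices are normalized (intracranial extraction, principal-axis
    orientation, crop and resize), converted to multilayer texture images
    (MTIs) by fusing Canny-style edge maps obtained from an automatic
    descending schedule of hysteresis double thresholds derived from the
    64-bin gradient-magnitude histogram, and represented by Harris corners
    carrying importance values (the MTI layer value at the corner). Corner
    sets of two images are matched under mobility constraints (mobility =
    reciprocal importance) by a minimum-cost maximum-cardinality bipartite
    assignment, and a similarity function over the matched pairs drives a
    K-nearest-neighbour classifier whose corner-response threshold and K
    are selected by stratified cross-validation. A seeded synthetic brain
    phantom generator makes the whole pipeline exercisable without any
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Classification, Visualization
RoxygenNote: 7.3.3
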