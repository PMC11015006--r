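Package: voxalign
Title: Correlative Light-Sheet / X-Ray MicroCT Volume Registration and
    Marker Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for correlating multiview light-sheet fluorescence
    volumes with X-ray microtomography volumes of the same specimen:
    staged volume compression (crop, block-mean binning, 8-bit
    conversion, channel summation), landmark-initialised block-matching
    registration with similarity-class robust fitting and dense
    displacement-field refinement, application of the merged transform
    to full-precision data, Otsu-threshold marker quantification within
    segmented tissue labels, specimen-shrinkage estimation, and
    checkerboard / target-registration-error quality control. Includes
    a seeded synthetic phantom generator producing paired multimodal
    volumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'volume.R'
    'io.R'
    'transforms.R'
    'blockmatch.R'
    'quantify.R'
    'qc.R'
    'phantom.R'
    'pipeline.R'
    'voxalign-package.R'
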