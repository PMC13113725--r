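Package: aortaquant
Title: Automated Aortic Quantification from CT Segmentations
Version: 0.1.0
Authors@R:
    person("Aorta", "Quant Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing workflow for quantifying the thoracic aorta from a
    binary segmentation of any upstream source: centerline extraction through
    the mask interior, curved planar reformation (vessel straightening) with
    rotation-minimizing frames, per-cross-section maximal (Feret) diameter and
    area profiles with Savitzky-Golay smoothing, anatomical subdivision into
    ascending aorta, arch and descending aorta, and threshold-based dilation
    detection. Ships spacing-aware segmentation comparison metrics (Dice, IoU,
    95% Hausdorff, average symmetric surface distance), method-agreement
    statistics (Pearson with Fisher-z CI, ICC(2,1), Bland-Altman) and ROC
    analysis with Youden operating points, plus a voxelized vascular phantom
    generator with exact analytic ground truth so the whole pipeline is
    testable without patient data. Reads and writes NIfTI-1 and NRRD volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
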