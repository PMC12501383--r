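Package: emipr
Title: Enhanced Maximum Intensity Projection for Raster-Scan Optoacoustic Mesoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image formation for dual-band raster-scan optoacoustic mesoscopy (RSOM)
    volumes. Implements automatic skin-surface detection (iterative tiled
    thresholding, penalized polynomial and RANSAC surface fitting with outlier
    exclusion), z-column flattening of the reconstruction to a fixed zero level,
    and dynamic dual-band contrast fusion into RGB renderings (eMIP), alongside the
    conventional alpha-equalized maximum intensity projection baseline. Includes a
    synthetic skin-phantom generator with known ground truth, readers and writers
    for float TIFF/NIfTI volumes and rating tables, and the rater-agreement
    statistics used to compare renderings: mean opinion scores, paired difference
    tests, and generalized weighted Fleiss' kappa with jackknife variances and
    agreement-gain tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
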