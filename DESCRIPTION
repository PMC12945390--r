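Package: subgen
Title: Subspace Generalization Analysis for Neural Population Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how well the low-dimensional linear subspace occupied
    by one task's population activity explains another task's activity, via
    the area under the normalized cumulative variance-explained curve of
    cross-projected principal components. Includes firing-rate-map
    construction from spike/position event tables, simulators for grid-cell
    modules (with coherent realignment across environments), remapping place
    cells and noisy pseudo-voxels, permutation/bootstrap/subsampling
    inference on AUC differences, and a cross-validated searchlight pipeline
    for run-by-condition beta volumes with max-statistic sign-flip
    familywise-error control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
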