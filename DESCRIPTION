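Package: xenoquant
Title: Quantification of Xenografted Tumor-Cell Proliferation in Zebrafish Embryo Micrographs
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated quantification of GFP-labeled tumor-cell burden in
    zebrafish embryo xenograft assays from two-timepoint fluorescence
    micrographs. Implements a per-image threshold sweep with automatic
    threshold selection that suppresses embryo yolk autofluorescence, a
    proliferation index built from GFP pixel area and mean intensity at 0
    versus 72 hours post injection, circular-Hough cell counting for
    injection-dose estimation, replicate survival summaries with IQR outlier
    filtering and homoscedasticity-gated two-group comparison, a batch driver
    over CSV manifests, and a synthetic phantom generator with ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
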