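Package: homnet
Title: High-Order Moment-Based Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs dynamic functional connectivity networks from
    region-of-interest (ROI) fMRI time series using sliding-window Pearson
    correlation, extracts order-d central-moment feature networks CM(d) that
    are invariant to the chronological order of the windows, and builds
    high-order networks Ho(d) by correlating the moment profiles of brain
    regions.  Includes a two-sample t-test + LASSO + linear SVM classification
    pipeline evaluated under repeated stratified nested cross-validation,
    majority-voting combination of network-specific classifiers, block-level
    summaries of connectivity between functional systems, and a synthetic
    cohort generator with controllable group differences in the moments of
    dynamic connectivity so the whole pipeline can be exercised without any
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
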