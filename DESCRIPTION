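Package: arbormetrics
Title: Morphometry of Arterial Centerline Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying branching patterns of arterial trees from
    centerline reconstructions with per-node radii. Reads SWC and node-table
    centerline files, splits trees into inter-bifurcation segments, estimates
    proximal and distal segment radii by a quartile-trimmed linear regression,
    and computes the standard branching-pattern statistics: area ratio,
    asymmetry ratio, length-to-radius ratio, tapering, and the minimum-work
    (Murray's law) compliance statistic and junction exponent. Includes robust
    regression with false-discovery-controlled outlier removal (ROUT), a
    Lilliefors-type normality test with Monte Carlo p-values, a synthetic
    vascular-tree generator with known ground truth and detection-radius
    censoring, and a full-width-at-half-maximum radius estimator validated on
    digital tube phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nortest,
    RNifti
Config/testthat/edition: 3
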