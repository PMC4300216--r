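Package: pollenclim
Title: Pollen-Climate Transfer Functions and Calibration-Set Bias Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and stress-testing pollen-based climate
    reconstructions. Fits weighted-averaging partial least squares (WA-PLS)
    transfer functions relating fossil pollen percentages to monthly mean
    temperatures, cross-validates them by leave-one-out and site bootstrap
    (RMSEP), screens calibration sets with the modern analog technique
    (squared chord distance), and quantifies the systematic bias introduced
    when a transfer function trained on one era's calibration set is
    hindcast onto another era's pollen. A synthetic-data module generates
    calibration sets from unimodal (Gaussian) taxon-climate responses,
    land-clearance disturbance scenarios, and varve-dated down-core records
    with known climate histories, so every stage of the pipeline can be
    validated against ground truth. Comparison utilities align down-core
    reconstructions with annual instrumental series and run the standard
    battery of mean, variance, trend and pairing tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
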