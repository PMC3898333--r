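Package: isletquant
Title: Islet Quantification by Cell Number and Islet Equivalents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying isolated pancreatic islet tissue. Implements
    the conventional islet-equivalent (IE) estimators (exact sphere, Ricordi
    50-micron binned, and density-expectation refined binning) alongside a
    cubic diameter-to-cell-number conversion model calibrated on dissociated
    rat islets, plus the calibration (polynomial fitting, ANCOVA, Pearson r,
    CV%), assay-normalization (per IE, per cell, per DNA) and Monte-Carlo
    simulation machinery needed to quantify how IE-based normalization
    overestimates the tissue volume of large islets while cell-number
    normalization does not. Includes CSV/YAML readers and writers, a
    spreadsheet-equivalent diameter-to-cell conversion table, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
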