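Package: nircal
Title: Online Calibration of Near-Infrared Spectra with Recursive
    Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and maintains quantitative near-infrared (NIR)
    calibration models for constituent analysis (e.g. fat content of
    nut samples) under batch drift. Implements online multiplicative
    scatter correction (OMSC) with a dynamic running-mean reference
    spectrum, uninformative variable elimination (UVE) wavelength
    selection with feature-set expansion and eigenvalue-based band
    monitoring, NIPALS partial least squares with cross-validated
    latent-variable selection, and recursive PLS (RPLS) model updating
    with a forgetting factor. Includes a seeded synthetic NIR study
    generator with known ground truth, delimited-text spectra I/O, and
    a command-line interface covering the simulate / preprocess /
    select-features / fit-offline / run-online / evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
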