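Package: coronakit
Title: Quantification of Aerotactic Ring Migration in Confined Cell Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying collective aerotactic migration in confined
    cell colonies from bright-field time-lapse imaging: adaptive binarization and
    radial density profiles, detection and kinetics of the dense outward-moving
    cell ring (the corona), expansion velocity of unconfined colonies,
    single-cell detection, nearest-neighbour track linking, radial
    directionality statistics and von Mises orientation fits. Includes an
    agent-based synthetic colony simulator (kinematic and oxygen
    diffusion-consumption mechanistic modes) that produces image stacks with
    known ground truth, so every estimator can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
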