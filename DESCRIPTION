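Package: octava
Title: Registration, Averaging and Change Analysis for OCT Angiography En-Face Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing repeated optical coherence tomography
    angiography (OCTA) en-face acquisitions of the retinal capillary plexuses.
    Registers sequential acquisitions to the first (similarity transform followed
    by B-spline elastic refinement), computes the average-intensity projection,
    quantifies per-pixel gain and loss of vessel signal between averaged and
    single images (difference maps, red overlays, 3x3 box scores), measures
    vessel density by automatic thresholding, and assesses repeatability of
    vessel-density measurements with intraclass correlation coefficients.
    Includes a synthetic angiogram generator (branching vessel trees, capillary
    mesh, speckle noise, motion-stripe artifacts, acquisition jitter, elastic
    deformation, intermittent capillary perfusion, cystoid darkening) with known
    ground truth, so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    Rcpp,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
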