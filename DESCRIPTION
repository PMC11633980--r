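Package: buscurate
Title: Curation and Cleaning of Clinical Breast Ultrasound Image Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for preparing clinical breast ultrasound (BUS) screenshot
    collections for AI model development. Flags invalid (near-black) frames
    and non-B-mode scans (Doppler blood-flow highlighting, elastography),
    detects burnt-in lesion measurement calipers and dual-view composite
    images, crops to the echo scan area with a two-stage shape-aware method,
    and extracts ACR BI-RADS labeling fields (laterality, transducer
    orientation, clock-face position, distance from nipple) plus procedural,
    measurement and axilla annotations from burnt-in text via a pluggable
    OCR backend and regular-expression grammars. Ships a synthetic phantom
    generator with machine-readable ground truth so every detector can be
    validated without clinical data, and an evaluation harness reporting
    per-task sensitivity, specificity and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
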