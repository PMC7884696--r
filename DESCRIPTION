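Package: lesiontopo
Title: Lesion Topology Analysis for Preclinical Stroke MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies ischemic stroke pathology from atlas-registered MRI
    masks and relates it to longitudinal motor outcomes in small preclinical
    cohorts. Computes canonical volumetrics (lesion volume, lesion percent of
    the ipsilateral hemisphere, hemispheric swelling/atrophy, midline shift),
    scores per-structure lesion burden against a brain parcellation atlas via
    percent-of-structure (PoS) and percent-of-lesion (PoL) voxel overlap,
    measures fractional anisotropy asymmetry in paired white-matter ROIs, and
    correlates structure-level damage with gait, open-field and modified
    Rankin Scale outcomes under Benjamini-Hochberg false-discovery-rate
    control. Includes a synthetic phantom-cohort generator with exact ground
    truth so the full pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
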