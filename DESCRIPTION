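Package: halluxmap
Title: Dynamic Distance Mapping of Hallux Valgus Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based morphometric analysis of hallux valgus on
    anteroposterior foot radiographs. Provides a canonical 24-landmark
    annotation schema, multi-annotator consensus merging with per-landmark
    dispersion, vector-geometry computation of the four standard clinical
    angles (HVA, IMA, DMAA, HIA), the full set of 276 pairwise Euclidean
    distances normalized by proximal phalanx length, Pearson correlation
    screening of distance features against the angles, severity
    classification, color-coded distance overlays and correlation heatmaps,
    and a parametric synthetic forefoot simulator with known ground-truth
    angles for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
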