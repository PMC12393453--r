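Package: capnet
Title: Quantification of Endothelial Calcium Activity in Skin Capillary Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify intravital calcium imaging of capillary
    endothelial cells: per-cell event calling from GCaMP fluorescence traces
    by windowed-minimum thresholding, persistent-activity detection on the
    0-255 intensity scale, multicellular cluster linking on vessel-surface
    grids, longitudinal conservation statistics for revisited cells,
    line-scan red-blood-cell flux analysis, vessel loop and skeleton
    morphometry, and dextran-extravasation permeability. Includes a
    synthetic-data generator with planted ground truth so every stage of the
    pipeline can be validated without raw microscopy.
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
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
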