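Package: micrassem
Title: Microfossil Assemblage Analysis from Automated Slide-Scan Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs microfossil assemblages from transmitted-light slide
    scans. Segments particle objects by binarization and connected-component
    labeling, extracts fixed-size crops with morphometry and an equivalent-
    diameter size filter, classifies crops into five categories (the target
    radiolarian Cycladophora davisiana, the look-alike C. bicornis, other
    radiolarians, centric diatoms, and other particles) with per-category
    confidence values and a confidence-threshold assignment rule, and derives
    assemblage statistics: per-category tallies, precision reports, count-based
    and averaged-confidence relative abundance of the target species, and
    linear calibration against manual expert counts. A synthetic-data module
    generates slide scans with ground truth and Dirichlet confidence tables so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    randomForest,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
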