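Package: parasegmentr
Title: Quantitative Analysis of Parasegmental Boundary Straightness in the
    Drosophila Germband
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying contractile compartment boundaries in the
    early Drosophila embryo: detection and tracking of nascent-transcription
    reporter dots, assignment of dots to tracked cells, classification of
    parasegments and of parasegmental-boundary (PSB), -1 and +1 interface
    columns, interface co-alignment statistics over developmental time
    (reflected orientation angles, LOESS time courses, two-sample
    Kolmogorov-Smirnov comparisons), fixed-embryo straightness and
    Myosin II line-trace enrichment ratios, and a multi-criteria in silico
    receptor screen. A synthetic-embryo generator with known ground truth
    drives testing and calibration end-to-end, so no raw microscopy data is
    required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    igraph,
    mgcv,
    EBImage,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
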