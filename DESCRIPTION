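Package: synapsemap
Title: Quantification of Immunological Synapse Patterning in T Cell-APC
    Couples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of 3D time-lapse fluorescence imaging of T cell-antigen
    presenting cell (APC) couples. Detects tight cell coupling from interface
    growth, classifies sensor accumulation at the immunological synapse into
    six mutually exclusive interface patterns (plus no accumulation) using a
    35 percent enrichment rule, standardizes cell shape onto a canonical
    half-spheroid for voxel-wise enrichment maps, measures lamella
    morphometrics (neck, lamellal length, shape factor), and aggregates
    cohorts into time-aligned pattern frequency, log2 central/invagination
    ratio and cumulative off-interface lamella statistics. Includes a
    ground-truthed synthetic 4D image generator emulating spinning-disk
    acquisitions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
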