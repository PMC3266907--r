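Package: delimtherm
Title: GMYC Species Delimitation and Thermal Tolerance Range Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single- and multiple-threshold Generalized Mixed
    Yule Coalescent (GMYC) species delimitation on ultrametric gene trees,
    with likelihood-ratio testing, entity extraction and confidence sets;
    uncorrected p-distance summaries within and among delimited species;
    intersection of occurrence records with sea surface temperature
    rasters to compute per-species thermal summaries including the
    maximum thermal tolerance range; and regression of thermal tolerance
    against log-transformed latitudinal and longitudinal range size.
    Includes seeded generators for synthetic trees, alignments, SST
    rasters and occurrence records so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
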