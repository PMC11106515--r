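Package: hicdelta
Title: Differential Analysis of Hi-C Chromatin Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Comparative analysis of binned Hi-C contact maps between two
    conditions: iterative correction (ICE) balancing, distance-decay statistics
    and interaction decay exponents, stratum-adjusted correlation coefficients
    for reproducibility, A/B compartment calling from the eigenvector of the
    observed/expected correlation matrix with switch classification, diamond
    insulation scores with TAD boundary calling and a differential-boundary
    rule, donut-filter focal loop calling with gained/lost classification and
    aggregate peak analysis, and coupling of each structural layer to a
    differential gene-expression table. Includes a seeded synthetic Hi-C and
    expression generator with planted ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
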