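Package: aquamiR
Title: Detection Filtering, Reference Selection and Differential
    Expression for miRNA RT-qPCR Ct Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of wide-format cycle-threshold (Ct) matrices from
    microRNA RT-qPCR array profiling of biofluids such as aqueous humor
    and plasma. Implements group-wise detection filtering with a
    configurable Ct ceiling, combined reference-miRNA selection from
    geNorm M, a NormFinder-type model-based stability value and a scaled
    coefficient of variation merged into a summarized stability score
    (SSS), dual-strategy normalization (global mean and endogenous
    references), consensus 2^-ddCt differential-expression calling,
    single-assay validation by Mann-Whitney testing, overrepresentation
    arithmetic for pathway count tables, and a synthetic Ct generator
    with planted ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
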