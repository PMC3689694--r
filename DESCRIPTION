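Package: polytrans
Title: Polysome Profiling Translatome Analysis via Ratio-of-Ratios
Version: 0.1.0
Authors@R: person("polytrans", "developers", role = c("aut", "cre"),
    email = "polytrans@example.org")
Description: Analysis pipeline for two-fraction (polysomal / total
    cytoplasmic) expression profiling of a knockdown-versus-control design.
    Computes per-replicate knockdown/control ratios, the relative
    translatability statistic RR (ratio of polysomal to total fold change),
    concordance-thresholded translational calls, and a mutually exclusive
    polysome-versus-total regulation classification (polysome-only change,
    translational buffering, opposite changes, concomitant change).
    Includes delta-delta-Ct qPCR quantification with housekeeping-gene
    normalization and a paired t test, 5'UTR GC/length distribution
    comparison by two-sample Kolmogorov-Smirnov tests, hypergeometric
    over-representation analysis, and a synthetic-data generator with
    planted ground truth for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
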