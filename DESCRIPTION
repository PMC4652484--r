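Package: hairpinBS
Title: Hairpin Bisulfite Read Simulation, Original-Sequence Recovery and
    Mapping Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying why bisulfite-converted short reads map
    poorly. Simulates hairpin bisulfite read pairs (a T-enriched and an
    A-enriched mate sequenced from the two strands of one DNA duplex)
    with configurable CpG/CpH methylation, incomplete conversion and
    sequencing error; reconstructs the original unconverted sequence
    from a mate pair via the hairpin rule table and calls per-strand
    methylation; maps converted and recovered reads with a minimal
    seed-and-extend mapper that has a three-letter (C-to-T / G-to-A)
    bisulfite mode and a brute-force oracle; and provides the
    downstream analyses: sequence entropy by mapping category,
    two-sample Kolmogorov-Smirnov comparisons, length and
    mismatch-location stratification, bootstrap comparison of converted
    versus recovered unique-mapping efficiency, cross-strand rescue,
    mapper union, and methylation-rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'hairpinBS-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'io.R'
    'mapper.R'
    'pipeline.R'
    'recover.R'
    'simulate.R'
    'stats.R'
    'utils.R'
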