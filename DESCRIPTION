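Package: flightomics
Title: Longitudinal Blood Transcriptome and m6A Epitranscriptome Analysis
    for Short-Duration Spaceflight Missions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for longitudinal blood multi-omics from
    short-duration crewed missions sampled at pre-flight, return, and
    recovery timepoints. Implements library-size normalization and
    gene-level z-scoring, pathway median z-trajectories, a permutation
    test for gene-set co-regulation, the dz disruption statistic (the
    deviation of the observed return-day pathway z-score from a linear
    pre-flight trend), site-level differential m6A methylation with
    hyper/hypo classification and recovery-reversal profiling, pathway
    methylation density, dual-quantifier concordance with a
    consensus differential-expression rule, and cross-crew per-timepoint
    unique-transcript detection over GffCompare-style catalogs. A
    negative-binomial synthetic-data generator with subject random
    effects and planted pathway, methylation, and transcript effects
    makes the whole pipeline testable end to end without raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
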