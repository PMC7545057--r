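Package: lactDGE
Title: Stage-Wise Differential Expression, Temporal Patterns, and Pathway
    Impact for Lactation Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for bulk transcriptome profiles
    collected across stages of the lactation cycle (peak lactation, dry-off,
    involution). Provides RPKM normalization and abundance classification,
    stage-unique gene detection, a random-variance-model moderated t-test with
    chi-square count testing and Benjamini-Hochberg FDR control, short
    time-series model-profile assignment with exact permutation significance,
    Pearson co-expression network hub-gene ranking, and Dynamic Impact Approach
    (DIA) pathway impact and flux scoring. Includes a seeded negative-binomial
    simulator with planted differential expression, temporal profiles, and
    enriched terms, so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
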