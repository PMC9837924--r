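Package: embryodyn
Title: Chromatin Accessibility and Transcriptome Dynamics During Wheat
    Embryogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for time-series regulatory genomics of allohexaploid
    wheat embryogenesis. Classifies accessible chromatin regions (ACRs)
    into promoter, genic and distal categories with a position-priority
    peak-to-gene assignment, tracks stage-wise gain/loss and transient
    distal-ACR bursts, computes observed/expected enrichment against
    shuffled intergenic backgrounds, orders genes along a PCA-based
    developmental-time-unit (DTU) pseudotime via angular ranking of
    standardized profiles, infers TF-target regulatory networks from
    motif hits filtered by co-expression, and classifies homoeolog triad
    expression bias and hexaploid-versus-ancestor divergence. A
    deterministic synthetic-data generator with planted ground truth
    makes the whole pipeline testable without any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
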