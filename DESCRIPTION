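Package: methylstage
Title: Stage-Resolved Differential DNA Methylation Analysis for Bisulfite
    Sequencing Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for base-resolution DNA methylation progression
    analysis across ordered disease stages from reduced-representation
    bisulfite sequencing (RRBS/ERRBS) call tables. Calls differentially
    methylated cytosines (DMCs) per stage with a pooled exact test,
    magnitude and q-value thresholds; merges dense DMC runs into
    differentially methylated regions (DMRs) using a mixture-based gap
    threshold; annotates loci to promoters, gene bodies and enhancers with
    permutation enrichment tests; performs hypergeometric gene-set overlap
    enrichment and methylation-expression integration; clusters the
    cross-stage DMR union into trajectory groups; and builds a signed
    co-methylation network with module detection, eigengenes and a
    permutation z-summary preservation statistic. Ships a synthetic
    ERRBS-like data generator with planted ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    withr,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
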