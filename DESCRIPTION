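Package: accuscore
Title: Mutation Accumulation and Consensus Pathogenicity Scoring for
    Somatic Variant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores genes in a somatic-mutation cohort by combining
    cohort-wide variant allele fractions with intermutation distances
    (an accumulation score rewarding recurrent, kataegis-like clustered
    mutation), and by a four-channel consensus of variant interpreters
    (InterVar, ClinVar, SIFT, CADD) summarised per gene and sample with
    pathogenicity classes. Provides population-frequency and consequence
    pre-filters, gene-set (GMT) aggregation for two-cohort comparison,
    recurrence matrices, a synthetic two-cohort data generator with
    ground-truth labels, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    GenomicRanges,
    ggplot2,
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
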