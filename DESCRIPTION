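Package: melpanel
Title: Somatic Variant Triage, Genomic Subtyping and Quality Control for
    Targeted Melanoma Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for custom targeted amplicon sequencing panels
    in primary melanoma. Implements a multi-stage somatic-variant triage
    cascade (region/consequence filtering, read-support thresholds, in-silico
    pathogenicity consensus voting, germline-polymorphism partition), TCGA
    four-class genomic subtyping (BRAF/RAS/NF1/triple-wild-type) with
    co-occurrence and mutual-exclusivity summaries, clinicopathological
    association statistics (Wald odds ratios, logistic and ordinal-trend
    models), panel coverage quality-control metrics, a binomial
    limit-of-detection model for dilution-series sensitivity assays, and a
    fully seeded synthetic-cohort generator so that every stage is testable
    without access to patient-level sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
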