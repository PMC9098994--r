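Package: lohcna
Title: Allele-Specific Copy-Number Aberration Calling, LOH Detection, and
    Survival Integration for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of allele-specific copy-number segment
    profiles (ASCAT-style) in tumor cohorts: ploidy-adjusted gain/loss
    calling, loss-of-heterozygosity (LOH) and copy-neutral LOH detection,
    genome instability index, projection of segment calls onto genes,
    genome-wide aberration frequency tracks with group-wise per-interval
    testing, contingency-table association statistics with false discovery
    rate control, copy-number versus expression integration with
    nearest-centroid molecular subtyping, and Kaplan-Meier / Cox
    proportional-hazards survival stratification by LOH and mutation
    status. Ships a synthetic-cohort generator with recorded ground truth
    so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
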