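Package: idmrscreen
Title: Screening and Validation of Candidate Imprinted Differentially
    Methylated Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for discovering and validating
    candidate imprinted differentially methylated regions (iDMRs) in
    bisulfite-sequencing methylomes. Counts allelically methylated region
    (AMR) records overlapping CpG islands, applies record-count and
    intermediate-methylation filters, and classifies candidates as gametic
    (maternal or paternal) or secondary from oocyte and sperm methylomes.
    Provides region-level methylation summaries and status calls, a
    trisomy parent-of-origin dosage model, methylation-sensitive
    restriction enzyme (MSRE) PCR proportion computation, categorical
    allele-specific expression (ASE) calling from allelic RNA-Seq read
    counts with cis-window scans and sample-unicity checks, trio-based
    inference of the parental origin of methylation imprints, and a
    synthetic-data generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
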