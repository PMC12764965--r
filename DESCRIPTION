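Package: methmap
Title: Integrative Methylation Mapping of Cancer Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolves differentially methylated regions (DMRs) found in
    cancer methylomes into changes driven by normal cell processes
    (proliferation history, differentiation) and changes truly specific to
    disease. Implements a simplified two-group DMR caller for Illumina-style
    beta-value matrices, cross-population effect profiling and rule-based
    category mapping (proliferation, differentiation, cancer-specific,
    cancer-absent, and per-disease specific/absent with an optional stringent
    fold criterion), descriptive characterization of DMR groups, Fisher's
    exact genomic-feature enrichment with Benjamini-Hochberg control, and
    methylation-expression integration to nominate candidate
    methylation-regulated genes. Ships a synthetic-data generator with
    planted ground truth so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
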