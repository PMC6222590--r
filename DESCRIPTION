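Package: artisel
Title: Selection-Signature Scans and Mixed-Model Association for Two-Population SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate artificial-selection regions in a focal
    population contrasted against one or more reference populations, and tests
    quantitative-trait association under a mixed model. Implements a
    SweepFinder-style composite likelihood ratio scan against the genome-wide
    site-frequency spectrum, per-site Weir-Cockerham F_ST averaged in 25-kb
    windows, empirical-percentile significance with 200-kb region merging and
    track intersection, and a leave-one-chromosome-out GRM mixed-model GWAS
    with a SimpleM effective-test-count threshold. Includes a synthetic-data
    generator (Balding-Nichols differentiation, hard-sweep site-frequency
    distortion, GBS-like missingness, batch-structured phenotypes) so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
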