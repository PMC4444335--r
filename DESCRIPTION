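Package: tampscape
Title: Fitness Landscapes of Telomeric Amplicons from Pooled Barcode Competition Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for genome-wide fitness screens of telomeric amplicons
    (Tamps) assayed by pooled chemostat competitions and barcode sequencing.
    Provides a seeded simulator of pooled competition dynamics with a
    three-barcode read structure and a strain-construction error model;
    demultiplexing, barcode counting and trajectory construction; per-replicate
    relative-fitness estimation by log-ratio regression with
    replicate-variance filtering and kernel-density-mode aggregation; a native
    circular binary segmentation engine for genome-ordered fitness profiles
    with Upstep/Downstep breakpoint classification; cross-condition region
    integration, candidate driver-gene filtering, amplicon fitness prediction
    and pleiotropy summaries; and exact Wilcoxon rank-sum and Fisher tests
    with Holm-Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
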