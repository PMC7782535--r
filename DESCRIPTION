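Package: mirclash
Title: CLASH Chimeric-Read Calling and AGO2-IP Target-Site Enrichment
Version: 0.1.0
Authors@R: person("mirclash", "developers", email = "mirclash@example.org",
    role = c("aut", "cre"))
Description: Identifies miRNA-mRNA chimeric (hybrid) reads from ligated
    AGO2-immunoprecipitate sequencing libraries and ranks candidate miRNA
    target sites by a local-enrichment statistic that contrasts read counts
    in extended target regions (TAR) against the remainder of the 3'-UTR
    (NT3UTR), compared between wild-type and miRNA-knockout samples.
    Includes paired-end read merging, adapter trimming, a contiguity filter,
    a seeded local aligner with Karlin-Altschul E-values, chimera selection
    rules, TMM count normalization, and a synthetic-data generator with
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
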