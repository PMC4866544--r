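Package: mpratag
Title: Allele-Specific Activity Analysis for Tag-Based Reporter Assays
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for massively parallel reporter assays that
    compare ancestral and derived alleles of transcription factor binding
    sites via 20-nt transcript tags. Covers the variant/construct library,
    tag extraction from construct-sequencing reads, tag-to-construct
    association and counting, background subtraction with reverse
    transcriptase minus controls, DNA-input normalization, per-replicate
    log-ratio statistics with robust replicate quality control, one-sample
    t-tests with Benjamini-Hochberg correction per cell line, signed
    fold-change conversion, cross-cell-line correlations, and a fully
    seeded synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
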