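Package: escapescreen
Title: Longitudinal Screening for Immune-Escape Drivers Under Checkpoint Blockade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying genetic drivers of acquired
    resistance to immune checkpoint blockade from longitudinal tumor
    whole-exome data. Combines per-caller somatic variant sets by consensus
    voting, builds force-called read-count matrices across a patient's
    biopsies, converts variant allele fractions to cancer cell fractions
    (CCF) with exact binomial confidence intervals and per-variant detection
    power, calls gene-level loss of heterozygosity (LOH) from allele-specific
    copy-number segments, and screens for genes whose non-silent mutations
    plus LOH are dominant only during disease progression. Also provides
    neoantigen binder classification from percentile ranks, cohort-level
    enrichment (one-sided Fisher) and survival (Kaplan-Meier / log-rank)
    endpoints, gene-set expression scores, and a synthetic tumor-cohort
    generator with planted escape lineages for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
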