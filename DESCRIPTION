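Package: melatomics
Title: Pan-Cancer Multi-Omics Integration of Melatonergic Gene Alterations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates differential-expression evidence for a panel of
    melatonergic genes across microarray and RNA-seq platforms into a
    consensus status score, and relates it to DNA methylation, somatic
    mutation, copy-number, survival, progression and pathway-enrichment
    layers. Provides TMM normalization helpers, a conditional
    negative-binomial exact test for counts, gene-level methylation
    consistency calling, Kaplan-Meier/Cox survival stratification
    (including mutation-by-expression subgroups), metastasis and stage
    comparisons, anchor-gene correlation screening with hypergeometric
    pathway enrichment, and a seeded synthetic multi-omics cohort
    generator so the whole pipeline can be exercised without access to
    controlled consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    edgeR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    limma
Config/testthat/edition: 3
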