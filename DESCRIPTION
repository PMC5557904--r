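Package: somase
Title: Somatic Allele-Specific Expression from Matched DNA and RNA Read Counts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates variant and reference read counts from matched
    tumor/normal exome and transcriptome data to quantify somatic variant
    allele fraction (VAF), classify allele-expression extremes (somatic
    over-expression, SOM-E, and somatic loss, SOM-L) with exact binomial
    tests under Benjamini-Hochberg false-discovery control, and relate
    allelic expression to functional annotation via nonparametric cohort
    statistics. Ships a ground-truth read-count simulator (negative-binomial
    coverage, purity dilution, beta-binomial allelic overdispersion,
    Gaussian-copula annotation scores) so every stage is testable without
    access-controlled data, plus a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
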