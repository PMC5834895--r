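Package: lofprev
Title: Loss-of-Function Allele Prevalence Across Species and Its
    Life-History Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the prevalence of loss-of-function alleles (stopgain,
    stoploss, frameshift) in transcript-space variant calls across metazoan
    species and correlates species means with life-history traits. Includes
    ORF prediction, codon-aware consequence classification, quality filters,
    core and hard-core essential gene sets, the per-individual LoF allele
    proportion statistic, Spearman/Benjamini-Hochberg trait correlations, and
    a synthetic multi-species data generator under mutation-selection balance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
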