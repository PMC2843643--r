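Package: demethpred
Title: Promoter CpG Content, Methylation, and Demethylating-Agent Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for relating promoter CpG density and basal DNA
    methylation to gene up-regulation after treatment with a demethylating
    agent such as decitabine. Provides CpG counting over a TSS-anchored
    2,700-bp promoter window and its six sub-bins, quantile-based promoter
    stratification, a bias-aware two-criterion up-regulation call
    (fold-change plus absolute delta expression), per-category signed-rank
    and hypergeometric enrichment statistics, a cross-validated logistic
    classifier of response with a label-permutation null, harmonization of
    external methylation scales, and a seeded synthetic-data generator
    emulating pooled multi-strain promoter datasets with a plantable
    response-probability surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    GenomicRanges,
    IRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
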