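Package: hetvig
Title: Heterosis Transcriptome Analysis from Parent-Parent-Hybrid RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression and expression-pattern analysis of
    inbred-parent / F1-hybrid trios from gene-level RNA-seq counts.
    Implements median-of-ratios normalization, a negative-binomial
    conditional exact test with Benjamini-Hochberg correction,
    classification of each gene into the twelve additive /
    expression-level-dominance / transgressive expression classes,
    phenotype heterosis statistics (mid-parent value, heterosis rate and
    an F1-vs-mid-parent significance test), gene-length-bias-aware term
    enrichment via the Wallenius noncentral hypergeometric distribution,
    and a negative-binomial trio simulator with per-gene class ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
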