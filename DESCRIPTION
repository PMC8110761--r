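Package: hybridexpr
Title: Inheritance of Gene Expression in Interspecific Hybrid Transcriptomes
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq count data from interspecific
    hybrids and their parental lines: negative-binomial Wald tests for pairwise
    differential expression with median-of-ratios normalization and
    Benjamini-Hochberg FDR control, six-category classification of hybrid
    inheritance modes (conserved, additive, parent-dominant, overdominant,
    underdominant), transgressive-gene filtering with over/under-expression
    bias tests, shared-DEG set logic across crosses, ortholog-mediated
    hypergeometric term enrichment, and a seeded negative-binomial count
    simulator with per-gene inheritance-mode ground truth so the whole
    pipeline is testable without external data.
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
    optparse
Config/testthat/edition: 3
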