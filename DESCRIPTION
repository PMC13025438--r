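Package: hubfunnel
Title: Cross-Species Consensus Hub-Gene Screening from Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a multi-level screening funnel for
    consensus hub genes in xenograft transcriptomics: two-group differential
    expression on a gene-level count matrix (negative-binomial Wald test with
    median-of-ratios normalization and Benjamini-Hochberg adjustment),
    hypergeometric over-representation against GMT gene-set collections,
    cross-species matching of top biological-process terms and
    symbol-identity ortholog intersection, confidence-filtered
    protein-protein interaction subnetworks with a dynamic score threshold,
    and five from-scratch topological screens (MCODE molecular complex
    detection, maximal neighborhood component, betweenness, bottleneck, and
    local clustering coefficient) whose intersection yields the consensus
    hub. A synthetic-study generator with planted differential expression,
    paired human/mouse annotations, and a planted network module makes every
    stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
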