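Package: reoresponse
Title: Relative Expression Orderings for Discriminating Treatment-Response Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates cancer-related from cancer-unrelated treatment-response
    genes in transcriptomic cohorts of rectal cancer treated with preoperative
    chemoradiation. Builds a landscape of within-sample relative expression
    orderings (REOs) that hold in every normal tissue sample across platforms,
    calls differentially expressed genes in individual cancer samples from
    reversals of stable orderings (reversal-pair Fisher statistics with
    Benjamini-Hochberg correction and coupled-pair filtering), contrasts
    per-gene deregulation frequencies between responder groups, performs
    rank-product group comparisons with concordance-scored list merging, and
    provides hypergeometric gene-set enrichment and protein-protein interaction
    neighborhood statistics. A synthetic cohort generator with planted ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
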