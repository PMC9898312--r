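Package: pathkey
Title: Pathway Enrichment and Network-Based Key Gene Discovery for
    Prioritized Candidate Gene Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a systems-biology workflow for evaluating the joint
    pathway-level behaviour of a prioritized candidate-gene list against
    per-gene differential-expression p-values.  Provides competitive
    (hypergeometric over-representation) and self-contained (SUMSTAT and
    SUMSQ permutation) gene-set tests on -log10 gene-wise statistic scores,
    Benjamini-Hochberg and Bonferroni multiple-testing control,
    cross-condition consensus calls, functional gene-network construction
    from weighted edge lists with degree-centrality subnetwork extraction
    and key-gene selection, group-wise score comparisons, and fully seeded
    synthetic-data generators with known ground truth for calibration and
    power assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
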