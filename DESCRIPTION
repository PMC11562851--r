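Package: pleiodrug
Title: Drug Repurposing from Shared Disease Genetics via Network Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes drugs approved for diseases that predispose to a
    target disease (e.g. breast cancer) by exploiting their shared genetics.
    Starting from locally correlated GWAS loci, gene-based association
    statistics and signed gene-regulation statistics, the package extracts
    per disease-pair "shared genes", links them to canonical pathways on a
    confidence-filtered protein-protein interaction network using
    personalized PageRank with degree-matched permutation nulls, links drug
    targets to the resulting shared pathways with the same machinery, and
    evaluates the prioritized candidates against an external drug list with
    a one-sided Fisher exact test (hypergeometric tail and conditional
    maximum-likelihood odds ratio). A synthetic-data module generates all
    input formats with planted gene-pathway-drug signal so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
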