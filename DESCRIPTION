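Package: tppin
Title: Core Protein-Protein Interaction Network Extraction by Global Link
    Significance Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the core backbone of a weighted, undirected
    protein-protein interaction network. Link weights are mean jackknife
    Pearson correlations of gene expression; per-link statistical
    significance is computed under a global null model that keeps the
    topology fixed and draws weights independently from the network's
    empirical weight distribution, conditioning on endpoint strengths.
    Links are then removed in descending p-value order under the
    constraint that designated anchor gene sets (e.g. a receptor complex
    and its downstream signalling components) stay connected, with
    percolation-style topology monitoring, link-weight-randomization
    robustness analysis, and hypergeometric over-representation testing
    of essential genes in the surviving network. A synthetic-data module
    generates networks, block-correlated expression matrices, anchor
    sets and essentiality annotations with planted structure so the
    whole pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
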