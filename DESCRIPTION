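Package: gcpnet
Title: Genetic Concept Profile Clustering with Interaction-Network Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage literature-plus-network analysis of disease genetics.
    Stage one builds weighted genetic concept profiles (GCPs) for disease
    concepts from document-level co-occurrence in a text corpus, scores groups
    of diseases with a cohesion statistic (mean pairwise inner product of
    unit-normalised profiles), attaches per-gene contribution percentages and
    permutation P-values, and explores the similarity structure by
    average-linkage hierarchical clustering and classical multidimensional
    scaling. Stage two validates gene shortlists on a reference-filtered
    protein-protein interaction background: high-throughput references
    supporting more than a cap of links are discarded, the seed subnetwork is
    extracted at path length two, and intermediate nodes are scored with a
    one-sample binomial-proportion z statistic against the background link
    rate. Includes synthetic-data generators with planted disease-pair and
    intermediate-node structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
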