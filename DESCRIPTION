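Package: mnQTL
Title: Behavioral-Ecology Interaction Networks of the Gut Microbiota and
    Their Host Genetic Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies pairwise microbial interactions (mutualism,
    antagonism, aggression, altruism) from single-snapshot abundance data
    using behavioral-ecology descriptors, validates them against
    co-culture/monoculture interaction strengths with growth-phase
    stratification, reconstructs significance-filtered per-host and
    cohort-average interaction networks, computes emergent network
    properties (connectivity, closeness, betweenness, eccentricity,
    eigenvector centrality, PageRank), maps host SNPs controlling those
    properties by genotype-dependent normal likelihoods with genome-wide
    permutation thresholds, decomposes SNP effects on end-point phenotypes
    into direct and microbiome-network-mediated paths, and provides a
    Monte Carlo power study comparing abundance-QTL with
    network-interaction-QTL detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    pracma,
    igraph,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
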