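Package: guildnet
Title: Interacting-Guild Networks from Probabilistic Species Co-Occurrence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates significant microbial co-occurrence and co-exclusion
    pairs into environment-driven, dispersal-driven and potential
    biotic-interaction classes, and builds signed "interacting guild"
    networks from the remainder. Pairs are classified with the exact
    probabilistic (hypergeometric) co-occurrence model on presence/absence
    data; non-random pairs are attributed with one-way ANOVAs of
    environmental covariates and a MANOVA of site coordinates over the
    pair-defined site groups; unexplained pairs form a signed,
    log-P-weighted network partitioned with the spinglass algorithm for
    networks with negative edges. Includes a spatially explicit
    metacommunity simulator with planted environmental niches, dispersal
    kernels and pairwise facilitation/exclusion, used as a ground-truth
    harness, plus rarefaction/occupancy preprocessing, variable-importance
    ranking, module and node metrics, and downstream guild statistics
    (chi-square residual contributions, PAM k-medoids clustering,
    occupancy/abundance contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    ape,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
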