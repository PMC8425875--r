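Package: mpinet
Title: Metabolite-Protein Interaction Networks for Tumor Subtyping and
    Metabolite Accumulation Scoring
Version: 0.1.0
Authors@R:
    person("MPI", "Maintainers", email = "maintainers@mpinet.dev", role = c("aut", "cre"))
Description: Builds and filters directed bipartite metabolite-protein
    interaction (MPI) networks, derives consensus-clustering tumor subtypes
    from principal components of core metabolite-interacting protein
    expression, transfers subtypes across cohorts with elastic-net
    classifiers, scores per-metabolite accumulation (deltaM) from producer
    and consumer fold changes on the directed network, runs ranked-list and
    single-sample gene-set enrichment (including an immune ImmuP score),
    predicts novel MPIs from network-topology features with a random
    forest, and ships seeded synthetic-data generators with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    glmnet,
    igraph,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
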