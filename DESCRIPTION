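Package: ConvergeNet
Title: Convergent Candidate-Gene Prioritization via Steiner Subnetworks and Pathway Crosstalk
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes disease candidate genes by convergent evidence across
    independent gene lists. Two seed gene sets (for example genes residing in
    copy-number-variant regions and genes curated from association studies)
    are each expanded into a connected protein-protein interaction subnetwork
    with a node-weighted Steiner-tree heuristic that recruits as few non-seed
    linker proteins as possible. Genes shared by the two subnetworks form a
    high-priority candidate table, optionally annotated with case-control
    differential expression. Subnetwork genes are then tested for pathway
    over-representation (one-sided hypergeometric test) and significant
    pathways are organized into a crosstalk map scored by the mean of the
    Jaccard and overlap coefficients, whose connected components define
    functional groups. A synthetic-data module generates interactomes, seed
    sets, expression matrices and pathway collections with planted structure
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    igraph,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: NetworkInference, GraphAndNetwork, Network, Pathways,
    DifferentialExpression, GeneSetEnrichment, SystemsBiology
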