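Package: herbnet
Title: Multiscale Network Diffusion for Herbal Medicine Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes herbal medicines and their constituent compounds
    against a disease by network propagation on a multiscale interactome
    joining protein-protein interactions, protein-to-biological-function
    annotations, and a function hierarchy. Diffusion profiles are computed
    by a biased random walk with restart with type-dependent transition
    weights; herbs are ranked by the correlation of their diffusion
    profiles with a disease profile and assessed by hypergeometric overlap
    enrichment. Includes over-representation analysis against GMT gene-set
    libraries, differential-expression filtering for transcriptome-based
    validation, top-k mechanism subnetwork extraction with GraphML and
    Cytoscape JSON export, and a synthetic data generator that plants an
    effective herb near a disease module so the whole pipeline can be
    benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
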