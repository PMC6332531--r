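Package: loctom
Title: Co-Localization Filtering and Locational-Topological Overlap
    Imputation for Protein Interaction Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Preprocesses protein-protein interaction networks using
    subcellular localization: filters a global interaction network to its
    co-localized subnetwork, scores protein pairs with the topological
    overlap measure (TOM) and its location-aware extension (LTOM), and
    imputes high-scoring candidate interactions to densify the network
    before module detection.  Includes a cohesiveness-guided greedy
    clusterer and Markov clustering, complex-catalog benchmarking
    (clustering-wise sensitivity, positive predictive value, geometric
    accuracy), hypergeometric gene-set enrichment with the
    overrepresentation score, scale-free degree-distribution fitting, and
    a synthetic generator of localization-annotated networks with planted
    modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
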