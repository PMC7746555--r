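Package: scnet
Title: Structural Covariance Network Analysis of Regional Cortical Thickness
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and compares group-level structural covariance networks
    from subjects-by-regions cortical thickness tables. Regional thickness is
    corrected for age, sex and global mean thickness by linear regression;
    interregional Pearson correlations are thresholded into binary undirected
    graphs over a range of network densities; small-world indices normalized
    against degree-matched rewired random networks, efficiency, transitivity,
    modularity and nodal degree/clustering/betweenness (with hub detection)
    are computed per density; and group differences are tested by subject
    label permutation with area-under-the-curve summaries across densities.
    Includes a seeded synthetic cohort generator with block-structured
    interregional covariance for validation and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    MASS,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, StructuralPrediction, Software
RoxygenNote: 7.3.3
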