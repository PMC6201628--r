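Package: herbmap
Title: Mapping Multi-Ingredient Herb Perturbations onto Disease Expression States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed perturbation signatures for multi-ingredient herbs
    from ingredient-target activation/inhibition tables, propagates them over a
    protein-protein interaction network with a two-step degree-normalised
    diffusion, and matches the resulting extreme-gene signatures against
    disease expression profiles using a bidirectional Kolmogorov-Smirnov
    enrichment statistic (connectivity-map style) with a permutation null.
    Includes a genetic-algorithm search for optimal herb combinations under
    clinical contraindication constraints, a hypergeometric test for
    herb-disease literature co-occurrence, seeded synthetic-fixture generators
    with planted ground truth, and plain-text readers/writers for edge lists,
    RNK profiles, GMT signatures and herb-library tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
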