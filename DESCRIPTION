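Package: soiltrophics
Title: Soil Trophic Network Inference Along Land-Use Intensity Gradients
Version: 0.1.0
Authors@R: person("Soil Networks", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds heuristic soil food webs (metawebs) from taxa inventories
    and a knowledge base of pairwise trophic interactions, infers trophic
    groups with a directed Bernoulli stochastic block model selected by the
    integrated complete-data likelihood criterion, computes standard food-web
    topology metrics (trophic levels, omnivory, link density, path lengths,
    energy-channel ratios), quantifies network beta-diversity with Hill-number
    node turnover, ordination (PCoA) and permutation F tests, and relates
    per-field metrics to a multicriteria land-use intensity index with linear
    mixed models. Ships a synthetic-data generator with planted block
    structure and land-use effects so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
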