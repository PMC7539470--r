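Package: stigmanet
Title: Pollen-Transfer Networks from Stigmatic Pollen Loads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds directed, weighted plant-plant pollen-transfer networks
    from per-stigma conspecific and heterospecific pollen counts, computes
    degree and hub-role statistics, detects modules by seeded Louvain
    optimisation with a resolution parameter and repeated-run consensus,
    and relates network properties to floral traits and community
    parameters through beta, Poisson and binomial mixed models and
    random-forest classification. Includes a synthetic-community generator
    with planted module structure so every stage can be validated against
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    glmmTMB,
    vegan,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
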