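Package: mutscreen
Title: Germline Mutation-Rate Inference from Lethal Mutation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-cell-division germline mutation rates in Drosophila
    melanogaster males from balancer-chromosome recessive-lethal screening data.
    Implements a cell-lineage coalescent simulator for sperm-sample genealogies
    through a configurable germline population trajectory (cleavage, primordial
    germ-cell bottleneck, stem-cell stage, spermatogenesis), a Poisson
    mutation-pattern likelihood over division intervals, maximum-likelihood rate
    estimation with nested likelihood-ratio hypothesis tests, a grid scan over
    germline-dynamics assumptions, the allelism (complementation) screen that
    turns raw line and cross counts into mutation patterns, and a forward
    simulator of complete screening experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
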