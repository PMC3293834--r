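Package: gimotif
Title: Genetic Interaction Filters for Minimotif Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Short linear motif (minimotif) scanners predict many false
    positives. This package filters putative minimotif source/target protein
    pairs against genetic interaction (GI) networks using three strategies: a
    direct-edge lookup, a bounded graph-neighborhood expansion ("GI-node"),
    and an ortholog-cluster extrapolation across species ("GI-HomoloGene").
    It includes parsers for generic and BioGRID-style edge lists, gene alias
    tables and HomoloGene-style flat files, an evaluation harness
    (sensitivity, selectivity, discrimination ratio, ROC/AUC, activity
    stratification, random-pair negative sets), a synthetic-world simulator
    with planted statistical structure for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
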