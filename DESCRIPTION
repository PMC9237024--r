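Package: ravkit
Title: Replicable Axes of Variation from Multi-Study Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds an index of Replicable Axes of Variation (RAVs) by
    pooling principal-component loading vectors from many independent
    gene expression studies, clustering them on Spearman distance with
    Ward agglomeration, and averaging each cluster into a reusable
    gene-space signature. RAVs are annotated with pre-ranked gene set
    enrichment results and frequency-weighted MeSH term scores, and new
    datasets are interpreted against the model through validation
    scores, per-sample scores, and metadata association. Includes a
    synthetic corpus generator (planted shared factors, bootstrap
    positive controls, gene-scrambled negative controls) for calibration
    and testing, plain-text model serialization, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    cluster,
    data.table,
    jsonlite,
    yaml,
    optparse,
    edgeR,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
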