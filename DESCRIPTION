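Package: fermnet
Title: Co-Occurrence Networks, Keystone Taxa, and Community Assembly for
    Fermentation Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired bacterial/fungal fermentation
    microbiome surveys. Builds Spearman co-occurrence networks with
    FDR-controlled edge selection, detects ecological modules by multiple
    modularity algorithms, classifies keystone taxa from within-module (Zi)
    and among-module (Pi) connectivity, quantifies network stability by
    simulated random node removal with secondary extinction, links module
    alpha diversity to metabolite concentrations, fits the Sloan neutral
    community model (migration rate, bootstrap confidence bands, taxon
    partitioning), computes the normalized stochasticity ratio (NST),
    ranks indicator metabolites with random forests and cross-validation,
    and ships a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
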