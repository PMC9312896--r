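Package: pbcnet
Title: Stage-Aware Network-Medicine Drug Repurposing for Primary Biliary Cholangitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis workflow for prioritizing disease genes and candidate
    repurposable drugs in primary biliary cholangitis (PBC), per histological
    stage. Relevance-scored seed genes are diffused over a protein-protein
    interaction network by a random walk with restart, a bagged
    positive-unlabelled learner ranks unlabelled genes and selects the top-K
    "likely positive" genes per stage, and seed and likely-positive gene sets
    are tested for drug and pathway over-representation with one-sided Fisher
    exact tests and Benjamini-Hochberg FDR control. A synthetic-data generator
    (scale-free interactome, planted disease module, stage-labelled scored
    seeds, GMT annotation collections) makes the whole pipeline testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
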