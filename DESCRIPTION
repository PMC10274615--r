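Package: darkpath
Title: Placing Understudied Proteins into Curated Pathway Context via
    Predicted Functional Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts functional interactions (FIs) between proteins from
    vetted binary pairwise feature channels using a random-forest
    classifier, and places understudied ("dark") proteins into the context
    of curated reaction-level pathways. For each protein, candidate
    "interacting pathways" are quantified with a binomial enrichment score
    (-log10 of the Benjamini-Hochberg FDR over the protein's predicted FI
    partners), fuzzy-logic Boolean-network simulation scores (activation
    and inhibition), and a literature annotation score based on embedding
    similarity between pathway descriptions and gene-matched abstracts.
    Includes odds-ratio vetting of feature channels, co-expression channel
    construction from read-count matrices, correlation-based validation
    statistics, and deterministic synthetic-data generators that emulate
    every external input so the full pipeline runs end-to-end offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ranger,
    pROC,
    pracma,
    edgeR,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
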