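Package: pcosnet
Title: PCOS-Ferroptosis Interactome Construction and Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a disease interactome for polycystic ovary syndrome (PCOS)
    extended with ferroptosis-associated genes from curated seed lists and
    STRING-style evidence-channel edge tables. Provides noisy-OR recombination
    of evidence-channel scores with a random-expectation prior, high-confidence
    edge thresholding, hub and articulation-node topology statistics, minimal
    novel-connector prediction for orphan seed genes, hypergeometric
    over-representation analysis with Benjamini-Hochberg false discovery rate
    control and weighted set cover term summarization, and process-specific
    subnetwork extraction with bridge-node identification. A synthetic-data
    generator with planted ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
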