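Package: prsenrich
Title: Topology-Based Pathway Enrichment with the Pathway Regulation Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Pathway Regulation Score (PRS), a topology-aware
    pathway enrichment method for microarray differential expression data.
    KEGG pathway descriptions in KGML format are parsed into deduplicated
    directed gene graphs (relations drive edges in signalling pathways;
    substrate/product chaining drives edges in metabolic pathways).
    Differentially expressed nodes are weighted by the number of significant
    downstream nodes reachable through significant intermediates, and each
    pathway is scored by summing fold-change magnitude times weight over
    significant nodes, normalised for pathway size. A hypergeometric z-score
    is computed for comparison, and pathway significance is assessed by a
    gene-level fold-change permutation test with Benjamini-Hochberg FDR
    correction. Includes a synthetic fixture generator (KGML pathways plus
    simulated expression) and a command-line driver for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    xml2,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr,
    optparse
Config/testthat/edition: 3
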