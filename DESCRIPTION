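Package: genesum
Title: Gene Set Function Summarization with Language Models and an
    Over-Representation Baseline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes the shared function of a gene set by building a
    token-budgeted natural-language prompt from per-gene descriptions
    (gene symbols only, curated narrative synopses, or controlled text
    rendered from Gene Ontology annotations), completing it against a
    pluggable language-model backend (including a deterministic offline
    mock), parsing the structured payload, and grounding the returned
    term strings to ontology identifiers via exact label and synonym
    matching. Ships a standard hypergeometric over-representation
    baseline with Bonferroni correction, and an ontology-closure-aware
    benchmark (precision, recall, F1, has-hit/has-top-hit, gene-set
    perturbation, description swapping, run-to-run Jaccard stability,
    exact Mann-Whitney comparisons), together with seeded synthetic
    fixture generators so the whole pipeline runs and is testable with
    no network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
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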