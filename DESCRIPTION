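Package: semcoh
Title: Semantic and Probabilistic Markers of Discourse Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies discourse coherence from text with a battery of 131
    semantic and probabilistic measures computed on three levels of meaningful
    units (lexical categories, subword tokens, sentences): averaged semantic
    similarity, distribution descriptors and wave dynamics of similarity
    series, semantic-graph properties, static and cumulative centroid
    analyses, and language-model perplexities. Evaluates which measures track
    human coherence ratings consistently across languages (Spearman
    correlation, per-feature FDR across languages, Pass/Uncertain/Fail
    verdicts), models coherence loss across the psychosis spectrum with
    ordered probit regression, computes rater agreement (ICC(2,k), weighted
    kappa) and partial Spearman correlations with symptom scales, and relates
    coherence to cortical functional-connectivity gradient dispersion via a
    simplified diffusion-map embedding. A deterministic synthetic-data module
    generates every input with planted structure so the full pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    igraph,
    jsonlite,
    stats,
    stringi,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
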