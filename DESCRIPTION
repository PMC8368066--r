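Package: seminfer
Title: Distributional Inference of Causative Verb Semantics Across Speech Genres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether the meaning contrast between causative
    and non-causative verbs can be inferred from raw word co-occurrences, and
    how much word-class and dependency-syntax annotation add, across speech
    genres (child-directed speech, adult conversation, written language).
    Provides session-organized CoNLL-U corpus handling with equal-token
    sampling, construction of annotation training layers (raw, word class,
    dependency subtrees as relation tags or lexical items), a deterministic
    skip-gram negative-sampling embedding trainer with order-dissolved
    contexts, pairwise cosine-distance discrimination scores against
    random-pair baselines, neighbor-joining clustering of embedding distances,
    Bayesian hierarchical regressions with crossed verb-level random slopes
    (with PSIS-LOO model comparison and Pseudo-BMA+ weights), bootstrap
    Shannon-entropy probes of verbal constructions, and a genre-parameterized
    synthetic corpus generator so the full pipeline is testable without
    external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    rjags,
    coda,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
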