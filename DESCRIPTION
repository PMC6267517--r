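Package: semvar
Title: Corpus-Based Semantic Ambiguity Measures from Latent Semantic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a latent-semantic-analysis space from a pre-segmented
    text corpus and computes per-word measures of lexical-semantic
    ambiguity: contextual diversity (the number of ~150-token contexts a
    word occurs in), semantic diversity (sign-reversed log mean pairwise
    cosine among a word's contexts), and semantic variability (the
    within-group to between-group cosine-distance ratio after spherical
    k-means clustering of a word's context vectors, with the cluster
    count selected by a 90% sum-of-squared-error reduction rule),
    together with its residual after log contextual diversity is
    partialed out. Includes a seeded generator of topic-structured
    synthetic corpora with planted homonymous, polysemous, and
    unambiguous words for validating that the measures separate
    homonymy from polysemy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
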