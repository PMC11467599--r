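Package: convomine
Title: Mining Social-Media Conversations About Burn First Aid
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for locating, filtering, and characterizing
    health-topic conversations (burn first aid) on social-media platforms.
    Provides a packaged search-term taxonomy with platform-aware boolean
    query composition and phrase matching; text normalization (symbol
    stripping, stopword removal, rule-based lemmatization); a dual-lexicon
    relevance filter built on skip-gram word embeddings with character
    n-gram inference for out-of-vocabulary tokens, nearest-neighbour
    lexicon expansion, averaged pairwise-similarity scoring, and empirical
    threshold calibration; fixed-K latent Dirichlet allocation topic
    modeling with multi-topic document assignment and overlap accounting;
    descriptive characterization tables (conversation purpose, burn-type
    crosstabs, yearly trends, term prevalence, parent-voice detection);
    and a seeded synthetic conversation-corpus generator with gold labels
    so every stage is testable without platform access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
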