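Package: emotopic
Title: Lexicon-Based Emotion Classification and Topic Mining for Microblog Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for mining public emotion from short
    social-media posts (Weibo-style microblogs). Implements cleaning and
    dictionary-driven segmentation of Chinese text, matching against a
    DUTIR-style affect lexicon (seven emotion categories, intensity levels
    1/3/5/7/9, polarity codes 0-3) with intensity-weighted per-document
    emotion profiles, latent Dirichlet allocation fitted by collapsed Gibbs
    sampling with perplexity and UMass-coherence model selection over a
    range of topic counts, dual-annotator validation statistics (Cohen's
    kappa, multi-class precision/recall/F1), and a synthetic-corpus
    generator with planted emotions, topics and posting-volume profiles so
    that every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
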