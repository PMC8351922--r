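Package: trendsent
Title: Trending Topics, User Involvement and Sentiment Dynamics in Microblog Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects top-k trending topics in a timestamped microblog stream
    over overlapping time windows, scores per-user topical involvement, tracks
    per-user and per-topic sentiment dynamics, and builds and evaluates
    positive/negative/neutral sentiment clusters (weighted entropy, semantic
    cohesion). Topics are inferred with a Twitter-style latent Dirichlet
    allocation model (one topic per tweet, per-word background switch) fitted
    by collapsed Gibbs sampling; sentiment is scored with a lexicon-and-rule
    valence engine of the VADER family. Includes a synthetic stream generator
    with planted ground truth so every pipeline stage is testable without any
    external corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
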