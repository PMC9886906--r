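Package: triread
Title: Triangle-Model Simulations of Oral Vocabulary Effects on Reading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a recurrent triangle (orthography-phonology-semantics)
    connectionist model of reading trained by backpropagation through time,
    together with an artificial-lexicon generator with controlled word
    frequency, rime consistency, orthographic neighbourhood, homophony and an
    imageability proxy. Provides the two semantic-reliance measures used in
    individual-differences work on reading aloud (the consistency-effect
    regression and the division-of-labour pathway ratio) and the statistical
    battery relating oral vocabulary size and exposure to reading performance:
    linear mixed-effects models with crossed random intercepts,
    likelihood-ratio model comparison, interaction regressions, and a
    maximum-likelihood structural (path) regression with CFI, RMSEA and TLI
    fit indices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
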