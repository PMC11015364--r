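Package: narrarec
Title: Hybrid Recommendation and Evaluation for Mental-Health Recovery Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a hybrid recommender for mental-health recovery
    narratives combining content-based item k-nearest-neighbour filtering over
    categorical narrative characteristics with biased matrix factorization
    (SVD and SVD++ trained by stochastic gradient descent), together with a
    complete offline evaluation suite: normalized mean absolute error, mean
    average precision per participant, intra-list diversity, item space
    coverage, and overestimation-of-unfairness across demographic groups,
    cross-validated and tracked over time. A synthetic rating-log generator
    reproduces the statistical structure of sparse Likert-scale feedback logs
    from digital mental-health trials so that every stage can be exercised
    without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
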