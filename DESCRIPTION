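Package: capnet
Title: Signed Ising Networks and Two-Mode Centrality for Risk and
    Protective Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates signed Ising networks over binary survey variables by
    nodewise L1-penalized logistic regression with extended-BIC model
    selection (the eLasso approach), assesses edge stability by
    nonparametric bootstrap, splits the factor-by-outcome coefficient block
    by sign into bipartite "protection" and "risk" networks, and ranks
    nodes by two-mode normalized degree and closeness centrality. Includes
    a Gibbs sampler and exact enumeration for binary Markov random fields,
    a survey-like data generator calibrated to published marginal
    distributions, and an end-to-end pipeline driver. Motivated by network
    analyses of social, economic and human capital as risk or protective
    factors for sexual violence across interpersonal spheres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
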