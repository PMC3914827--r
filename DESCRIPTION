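Package: ktom
Title: Recursive Theory-of-Mind Agents and the Evolution of Strategic Sophistication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates meta-Bayesian theory-of-mind (k-ToM) learners of increasing
    recursion depth, together with reinforcement-learning and mixed-Nash phenotypes,
    playing iterated competitive ("hide and seek") and cooperative ("battle of the
    sexes") 2x2 games. Monte-Carlo averaged payoff matrices are fed into replicator
    dynamics to locate evolutionarily stable phenotype mixtures and to map how the
    stable state depends on the proportion of cooperative encounters and on the
    number of game iterations. Includes behavioural metrics (prediction-accuracy
    slopes, thresholded prediction rates, attributed sophistication levels), a
    reproducible experiment driver, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
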