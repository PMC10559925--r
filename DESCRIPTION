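Package: bwoig
Title: Wrapper Gene Selection with Black Widow Optimization and Iterated Greedy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for labelled gene-expression matrices
    using the black widow optimization (BWO) metaheuristic, an iterated greedy
    (IG) destruction-construction local search with a constant-temperature
    simulated-annealing acceptance rule, and their hybrid (BWO-IG). Candidate
    gene subsets are scored by stratified k-fold cross-validated k-nearest
    neighbour error combined with a subset-size penalty. Includes delimited-text
    loaders for expression matrices, a synthetic-data generator with planted
    class-informative genes, an exhaustive-search oracle for small feature
    spaces, and a multi-seed experiment harness with Welch t-test reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    class,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
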