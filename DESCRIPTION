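Package: swarmnas
Title: Swarm-Intelligence Architecture Search for Fundus Image Severity Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tailored deep ConvNet (TDCN) architecture search for severity
    classification of retinal fundus images using two swarm algorithms: an
    ant-colony-system search over an incrementally expanded pheromone graph
    of layer choices, and a particle-swarm search in which particles are
    layer sequences moved by probabilistic block-copying from personal and
    global bests. Includes the constrained layer-sequence calculus (exact
    search-space cardinalities, structural validation and repair), a
    lightweight CNN trainer used as the fitness evaluator, evaluation
    metrics (accuracy, one-vs-rest AUC, Cohen's kappa) with stratified
    k-fold cross-validation, and a synthetic fundus-like image generator so
    the whole pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
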