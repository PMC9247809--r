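Package: vaemmine
Title: Two-Phase Mining of Vaccine Adverse Event Mentions from Social Media Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Isolates rare vaccine adverse event mentions (VAEMs) -- personal
    health mentions in a vaccine context -- from large streams of short
    social-media posts.  Implements a two-phase pipeline: latent Dirichlet
    allocation topic models are trained, scored by how strongly they
    concentrate a small labeled VAEM sample into few topics
    (label-concentration F1), and applied as a one- or two-stage filter;
    the filtered, far less imbalanced stream is then classified with
    classical bag-of-words models (logistic regression, linear SVM, NBSVM,
    random forests, gradient boosting and a majority-voting ensemble).
    Includes a synthetic labeled corpus generator for end-to-end testing,
    skip-gram word embeddings, and funnel/effectiveness accounting of the
    stage-by-stage retention arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    stringi,
    jsonlite,
    glmnet,
    e1071,
    ranger,
    xgboost,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
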