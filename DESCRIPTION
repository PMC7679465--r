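Package: hyperprox
Title: Hyperbolic Geometry of Temporal Human Proximity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the latent-geometry analysis of temporal (close-range
    proximity) contact networks. Generates synthetic temporal networks with
    the dynamic-S1 model, in which every snapshot is an independent
    realization of the S1/H2 random hyperbolic graph model over fixed node
    coordinates; embeds time-aggregated contact graphs into the hyperbolic
    plane by Laplacian-Eigenmaps initialization and likelihood maximization;
    and evaluates the resulting maps through greedy routing on the temporal
    network, geometric link prediction, and susceptible-infected epidemic
    arrival-time analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
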