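Package: plasticnet
Title: Graphical Lasso Network Reconstruction and Hub-Gene Nomination
    for Plastic Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised co-expression network analysis for two-state
    (naive versus plastic) transcriptome experiments, modelled on the
    supraoptic nucleus microarray design: per-gene pooled-variance t tests
    calibrated against random-matrix null thresholds, top-K differential
    gene selection, sparse precision-matrix estimation by a from-scratch
    graphical lasso (block coordinate descent), a parallel Pearson
    correlation network, fan-out ("richness") filtering, network
    intersection and degree-based hub-gene nomination. Includes a
    synthetic-data generator with planted hub-structured Gaussian
    graphical dependencies so the whole pipeline is testable at desk
    scale, and condition-number diagnostics for near-singular covariance
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite, igraph
Suggests: testthat (>= 3.0.0), withr, xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
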