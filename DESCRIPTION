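Package: connstack
Title: Spanning-Tree Enhanced Connectivity Stacks for Brain-Network Classification
Version: 0.1.0
Authors@R:
    person("Fatima", "Benali", email = "fbenali@example.org", role = c("aut", "cre"))
Description: Builds three-channel "RGB-mimicking" functional connectivity
    stacks from parcellated resting-state fMRI time series and classifies
    subjects under stratified 10-fold cross-validation. Connectivity is
    estimated per subject by Pearson correlation, (shrunk) covariance, or
    tangent-space embedding relative to a group geometric mean of covariance
    matrices. The enhanced stack layers the original connectivity matrix with
    its maximum and minimum spanning trees (Kruskal), proxies for over- and
    under-connectivity patterns; the plain stack splits the matrix into three
    row bands. A transfer-learning workflow (frozen convolutional backbone,
    dropout head, optional low-learning-rate fine-tuning) performs the binary
    classification; a small trainable convolutional backbone is included, and
    the geometry of seven standard ImageNet architectures is modelled exactly
    for feature-map size analysis. A synthetic-cohort generator with planted
    over-/under-connected edges makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
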