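Package: cogniconn
Title: Multimodal Connectome-Based Prediction of Cognitive Performance
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Graph-theoretic feature extraction from functional and
    structural brain connectomes (within-, inter-network and ratio nodal
    connectivity on a 400-node, 7-network parcellation), surrogate-based
    edge significance filtering, PCA-derived cognitive composite targets,
    and a repeated nested cross-validation engine with confound
    regression, multimodal concatenation and fold-preserving stacking
    with a random-forest meta-estimator. Ships a synthetic-cohort
    generator emulating an older-adult imaging cohort so the full
    pipeline is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite,
    data.table,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
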