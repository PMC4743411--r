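Package: mlefflux
Title: Multi-Label Profiling of BCRP and P-glycoprotein Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Collates heterogeneous compound-transporter bioactivity records
    into consensus binary label matrices, computes an interpretable molecular
    descriptor panel and fingerprints, and fits multi-label classification
    models (label-powerset, binary relevance, classifiers chain) for the ABC
    efflux transporters BCRP (ABCG2) and P-glycoprotein (ABCB1). Includes
    interpretation tools (bagged-tree feature importance, descriptor threshold
    scans, a fixed two-descriptor selectivity rule, Bemis-Murcko scaffold
    pharmacology profiles) and a fully controlled synthetic-data generator so
    the whole pipeline is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    nnet,
    randomForest,
    rpart,
    e1071,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
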