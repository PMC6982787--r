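Package: admetnet
Title: Multitask Graph Convolutional and Fingerprint Networks for
    Physico-Chemical ADMET Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling physico-chemical ADMET endpoints (logD,
    aqueous solubility, melting point, membrane affinity, serum albumin
    binding) from chemical structure. Implements assay preprocessing
    (inequality-qualifier adjustment, replicate averaging, unit and log
    transforms, per-task standardization into a sparse compounds x tasks
    label matrix), molecule standardization and featurization (folded
    circular count fingerprints and molecular graphs with 75 atomic input
    features), fully connected networks with a count-mimicking input-noise
    scheme, Duvenaud-style graph convolutional networks with mean/max
    readout, masked multitask losses with simple or balanced task
    weighting, leave-cluster-out, matched-random and time-based validation
    splits, regression metrics, and a general-solubility-equation
    consistency audit. A synthetic-data generator produces valence-valid
    molecules and correlated multi-endpoint assay tables so the whole
    pipeline can be exercised without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    ChemmineR,
    ChemmineOB,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    glmnet,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
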