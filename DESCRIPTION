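Package: IPoCnet
Title: Responder Stratification and Signed miR-Target Network Analysis for
    Ischaemic Conditioning Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for responder/non-responder analysis of
    ischaemic post-conditioning experiments: troponin-based stratification of
    the post-conditioned arm via a two-component log-scale Gaussian mixture,
    negative-binomial Wald differential expression of miRNA count matrices
    with median-of-ratios normalization, discretization of contrasts into
    regulation calls and selection of miRs with a protective (conditioning-
    reversed) expression pattern, construction of a signed bipartite
    miR-target network with per-target node strength, and extraction of the
    mitochondria-related subnetwork after multi-identifier reconciliation
    against an IMPI-style annotation. A synthetic-data module generates every
    input with planted ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    SummarizedExperiment,
    S4Vectors,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    MASS,
    DESeq2,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
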