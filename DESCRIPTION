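Package: lungregnet
Title: Multi-Omic Regulatory Network Inference for Lung Adenocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers per-module directed gene regulatory networks from
    matched tumor/normal expression, promoter methylation, somatic
    mutation, transcription-factor target and lncRNA-protein binding
    data. Differentially expressed genes are clustered into weighted
    co-expression modules via topological overlap; directed edges
    within each module are learned by score-based Bayesian network
    hill climbing with bootstrap edge strengths, merged with curated
    TF-target interactions, filtered by lncRNA binding scores and
    promoter hypermethylation, and scored for robustness by random
    node deletion. Key transcription factors are ranked by target
    enrichment (odds ratio, Fisher exact test) combined with mutation
    significance, and key lncRNAs by retained regulatory out-edges
    with binding support. A synthetic multi-omic generator with
    planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
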