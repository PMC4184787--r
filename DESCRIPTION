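Package: neutract
Title: Neutrophil Activation Transcriptomics: Specificity Screens, Pattern
    Clustering, and Regulatory-Model Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for population-level gene expression profiles
    of mouse neutrophils and other immune populations. Implements a
    lineage-specificity screen over population-mean expression (presence and
    fold criteria, with the symmetric under-expression screen), a
    multi-criterion activation-gene filter (presence, one-way ANOVA,
    pairwise fold change, replicate coefficient of variation),
    K-means clustering of expression patterns with a sample-wise
    randomization validity control and correlation-preserving cluster
    merging, and regulatory-model enrichment: a permutation null over
    coarse-module bins and a regulator-target-pair chi-square test, combined
    into a dual-criterion regulator selection and a regulator-by-cluster
    P-value matrix with hierarchical clustering. A synthetic-data generator
    with planted ground truth makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
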