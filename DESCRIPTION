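Package: driverrank
Title: Master-Regulator Prioritization by Fusing Transcriptional and
    Protein-Interaction Network Degrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers condition-specific transcriptional regulatory networks
    from expression data constrained by a transcription-factor binding
    prior, using an exhaustive conditional-mutual-information parent-set
    search with a chi-square-penalized score on tertile-binned expression.
    Computes transcription-factor degree in the inferred network and in a
    context-independent protein-interaction network, fuses the two degree
    ranks into a combined score S = (R_T + R_P)/2, and evaluates ranked
    regulator lists for enrichment in known driver genes (ROC/AUC,
    Wilcoxon rank-sum, Kolmogorov-Smirnov, top-k Fisher exact tests).
    Includes preprocessing (missing-value filtering, k-nearest-neighbor
    imputation, growth-score sample selection, binding-prior filtering),
    post-processing of weighted-network z-scores against a randomized
    control, a ground-truthed synthetic benchmark generator, and an
    end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
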