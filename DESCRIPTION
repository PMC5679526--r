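Package: loopmed
Title: Causal Mediation Analysis of miRNA-TF-Gene Closed Regulatory Loops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers closed regulatory loops (a miRNA targeting both a
    transcription factor and a gene, with the transcription factor
    targeting the same gene) from regulator-target tables, screens loop
    edges with Pearson and distance correlation, estimates average causal
    mediation effects (ACME), average direct effects (ADE) and total
    effects per loop with nonparametric bootstrap uncertainty and linear
    sensitivity analysis, classifies mediated loops by which regulator
    carries the effect, and tests k-node network motifs against a
    degree-preserving random-graph ensemble.  Includes a seeded synthetic
    data generator with planted mediation structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    igraph,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
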