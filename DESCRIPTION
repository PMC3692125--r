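Package: cmlink
Title: Pairwise Comparison of RNA Covariance Models via Link Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the specificity of RNA family covariance
    models (profile stochastic context-free grammars in the Infernal CM
    format). Parses and writes Infernal 1.0 and 1.1 ASCII model files,
    computes optimal (CYK) bit scores of sequences against single models,
    and for any model pair finds the Link sequence - the single sequence
    scoring highest in both models simultaneously - whose lower of the two
    model bit scores is the Link score. Includes one-vs-many and all-vs-all
    comparison workflows, result filtering, score matrices, weighted-graph
    (DOT) output for Rfam clan-candidate screening, brute-force oracles for
    validation, and a synthetic toy-model generator for testing.
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
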