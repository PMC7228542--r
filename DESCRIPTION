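Package: rdstreeboot
Title: Tree Bootstrap Inference for Respondent-Driven Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates respondent-driven sampling (RDS) as a Markov
    tree-indexed random walk on a hidden population graph, computes the
    standard RDS point estimators (sample mean, inverse-probability-weighted
    Horvitz-Thompson, and Volz-Heckathorn), and estimates their sampling
    uncertainty with the tree bootstrap: resample seeds with replacement,
    then recursively resample each node's recruits with replacement.  On
    complete m-ary recruitment forests the full bootstrap distribution can
    be enumerated exactly.  Includes a stochastic-block-model population
    generator with a critical-threshold check, file formats for graphs and
    recruitment forests, a command-line interface, and an experiment
    harness that measures bootstrap consistency empirically via the
    Kolmogorov distance between the centred bootstrap law and the Monte
    Carlo sampling law, together with confidence-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
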