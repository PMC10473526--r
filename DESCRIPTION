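Package: ideonet
Title: Causal Trait Networks, Yield Interventions and Ideotype Optimisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns causal trait-trait networks from multi-trait plant phenotype
    panels by BIC-scored Tabu search over Gaussian Bayesian networks under
    hierarchy constraints, with bootstrap arc probabilities and cross-fold model
    averaging. Fits per-node Gaussian-process regressions with an automatic
    relevance determination kernel, propagates do-interventions on single traits
    through the network to predict yield consequences, and proposes high-yield
    ideotypes by batch Bayesian optimisation (Expected Improvement with the
    Constant Liar heuristic) under principal-component correlation constraints.
    Also quantifies how trait-trait relationships distort broad-sense
    heritability estimates and genetic-association power, including a
    mediated-pleiotropy simulation with raw versus residual association scans.
    A synthetic-data module generates trait tables and genotype-trait datasets
    with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
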