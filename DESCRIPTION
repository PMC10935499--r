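Package: fedomics
Title: Cross-Silo Federated Learning Simulation for Multi-Omics
    Case-Control Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates cross-silo federated learning on tabular
    multi-omics case-control cohorts. Provides a synthetic cohort
    generator with genetic, transcriptomic and clinico-demographic
    feature blocks, client sharding under three heterogeneity regimes
    (uniform stratified, uniform random, linear random), federated
    training with FedAvg and FedProx aggregation over four local
    learner families (logistic regression, linear SGD, multilayer
    perceptron, boosted forest), a ten-metric evaluation suite under
    stratified K-fold cross-validation with internal and external test
    sets, and reproducible experiment arms comparing central with
    federated training, sweeping client dispersion, and crossing split
    heterogeneity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    ranger,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
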