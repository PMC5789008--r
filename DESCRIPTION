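Package: genoclim
Title: Gene-by-Climate Interaction Analysis of Population Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a composite dopaminergic gene-system index from
    sample-level allele frequencies (size-weighted aggregation, pairwise
    correlation, positive-semidefinite smoothing, principal components,
    Tucker congruence, composite reliability, 0-100 scaling), computes a
    climatic-demand index from monthly temperature extremes, and tests
    gene-by-environment interaction hypotheses on population trait means
    with mean-centred moderated regression, incremental F tests, simple
    slopes, percentile bootstrap, hierarchical control models, multivariate
    outlier screening and multiple-testing adjustment. A synthetic-data
    generator reproduces the statistical structure the analysis assumes, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
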