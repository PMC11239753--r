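Package: mliswd
Title: Power and Sample Size for Multilevel Intervention Stepped Wedge Designs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design and power analysis for hybrid trials that combine
    cluster-level randomization in a stepped wedge with independent
    individual-level randomization inside clusters. Builds marginal (GEE)
    mean models with average or incremental intervention effects for the
    individual-level, cluster-level and interaction components, block
    exchangeable and autoregressive working correlation structures, and the
    model-based covariance of the coefficient estimator; computes Wald-test
    power for arbitrary contrasts under chi-square or small-sample F
    reference distributions with Bonferroni multiplicity plans; searches
    cohort sizes and cluster numbers to meet power goals; handles incomplete
    designs through incidence matrices; and validates the analytic engine by
    Monte Carlo simulation with a generalized-least-squares estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
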