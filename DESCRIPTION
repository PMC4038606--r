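Package: demarch
Title: Demography and the Genetic Architecture of Complex Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time, independent-sites Wright-Fisher simulation of
    deleterious variation under step-wise demographic histories (bottleneck,
    bottleneck plus explosive recent growth, ancient growth), coupled to an
    Eyre-Walker-style model linking selection coefficients to quantitative
    trait effect sizes, a liability-threshold case-control sampler, and
    single-marker Fisher exact association testing. Provides tidy tabular
    summaries of segregating deleterious variation, genetic load, additive
    genetic variance partitions by allele frequency, mutation age, and
    association P-value, and the expected yield of case-control association
    studies under different population histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
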