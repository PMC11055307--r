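Package: epipower
Title: Power Analysis for LD-Based Detection of Gene-Gene Interaction in
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models statistical epistasis between two unlinked disease loci
    as extra linkage disequilibrium (LD) among affected chromosomes, and
    provides a design-stage power calculator for the case-control test of
    that extra LD at linked marker loci. Includes closed-form haplotype and
    marker-cell frequency derivations for case, control and population
    strata, the expectation and variance of the case-minus-control LD
    effect-size estimator, a 1-df chi-square interaction test with analytic
    noncentral chi-square power, the regular single-site allele-frequency
    association test for comparison, Bonferroni multiple-testing helpers,
    preset scenario grids, and a seeded multinomial Monte Carlo simulator
    that validates every analytic quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
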