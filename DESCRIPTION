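Package: trioskat
Title: Family-Based Sequence Kernel Association and Burden Tests for Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transmission-conditioned region-based association tests for
    quantitative (and dichotomous) traits in parent-offspring trios: a
    family-based sequence kernel association test (SKAT), an FBAT-style
    burden test, and the exchangeable rho-kernel family interpolating
    between them. Offspring genotypes are centered at their Mendelian
    expectation given parental genotypes, which makes the score test robust
    to population stratification. Includes mixture-of-chi-square p-value
    numerics (characteristic-function inversion with moment-matching
    fallback), pedigree/VCF/region input handling, a trio cohort simulator
    with configurable rare-variant architecture, empirical type-I-error and
    power studies over scenario grids, and a binomial GEE comparison of
    power across scenarios.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
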