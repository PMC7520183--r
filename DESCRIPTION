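Package: dietspec
Title: Cross-Sectional Diet Specialization from Scat Metabarcoding
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies intrapopulation feeding diversity in wild predators
    from DNA-metabarcoding diet profiles of scat. Converts prey read counts
    to compositional diet proportions, calls depositor sex from replicated
    ZFX/ZFY qPCR amplification patterns, forms location-by-sex-by-time groups,
    computes the proportional similarity index (PSi) of each sample against
    its group diet together with theoretical minima, Shannon-Weaver diversity
    and Monte Carlo confidence intervals, compares linear mixed models of
    logit-transformed PSi by AIC and Akaike weights with marginal and
    conditional r-squared, and runs Spearman correlations between prey-order
    proportions and specialization. A Dirichlet-multinomial study simulator
    with known specialization structure supports end-to-end testing, and
    packaged summary tables from a Salish Sea harbor seal study support
    reproduction of its headline statistics.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
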