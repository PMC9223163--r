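Package: marzic
Title: Marginal Mediation Analysis for Zero-Inflated Compositional Mediators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal mediation analysis for zero-inflated compositional
    mediators such as microbiome relative abundances. Models each taxon
    marginally with a zero-inflated Beta distribution, accounts for false
    (undersampling) zeros through a limit-of-detection likelihood, and
    decomposes the natural indirect effect into an abundance component and
    a presence/absence component under the potential-outcomes framework.
    Includes delta-method and bootstrap confidence intervals, per-taxon
    screening with Benjamini-Hochberg false discovery rate control, and
    simulators for zero-inflated Beta and zero-inflated
    Dirichlet-multinomial study designs.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
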