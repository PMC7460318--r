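Package: minemicro
Title: Heavy-Metal Pollution Indices and Microbial Community Analysis for
    Mining-Impacted Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for soils flanking mining-area rivers:
    Hakanson contamination factors, potential ecological risk index (RI) and
    the Nemerow comprehensive pollution index (PN) with grade classification;
    alpha diversity (observed species, Chao1, Shannon, Simpson) and exact
    rarefaction curves on OTU tables; Bray-Curtis dissimilarity, principal
    coordinate analysis, shared-OTU (Venn) accounting and UPGMA similarity
    clustering; redundancy analysis with Monte Carlo permutation tests,
    forward selection and variance partitioning; Spearman and Pearson
    environment-taxon correlation tables with significance stars; and a
    seeded synthetic-scenario generator (distance-decaying metal gradients,
    vegetation-dependent covariates, Dirichlet-multinomial communities) so
    the whole pipeline runs and validates without field data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
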