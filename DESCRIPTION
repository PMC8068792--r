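Package: ssrpop
Title: Genetic Diversity and Population Structure Analysis of SSR Germplasm Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing codominant microsatellite (SSR) genotype
    panels from germplasm collections: GenAlEx-style input and output,
    per-locus and per-group diversity indices (allele and genotype richness,
    Shannon-Wiener index, Nei's gene diversity, evenness E5), distance-based
    one-way AMOVA with PhiPT, permutation tests and gene-flow estimates,
    a simplified admixture-model Gibbs sampler with Evanno delta-K model
    selection, discriminant analysis of principal components (DAPC) with
    BIC-guided cluster detection and cross-validation, pedigree parent-usage
    summaries, and a Balding-Nichols simulator of structured SSR panels for
    validation. All user-facing functions return tibbles or objects with
    broom-style tidy() and glance() methods and ggplot2 autoplot() support.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
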