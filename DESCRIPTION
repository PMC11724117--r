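Package: mpgwas
Title: Multi-Population GWAS for Inbred Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association analysis across multiple
    inbred plant-breeding populations. Implements plot-level linear mixed
    models with genomic, residual-line, genotype-by-environment and
    spatial moving-window effects fitted by average-information REML;
    single-population and joint univariate (MP1) / multivariate (MP2)
    single-SNP association tests combined through a scaled Wald statistic
    that accounts for correlated estimation errors between populations;
    VanRaden genomic relationship matrices, kinship-corrected linkage
    disequilibrium and linkage phase similarity; heritability and
    proportion of variance explained; theoretical detection power from
    non-central chi-square non-centrality parameters; and a simulator of
    multi-population breeding programmes (biparental crosses, doubled
    haploids or single-seed descent) for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), lme4, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
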