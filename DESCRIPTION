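Package: salimpute
Title: Pedigree-Based Genotype Imputation and Genomic Prediction for
    Two-Generation Aquaculture Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-generation salmon-style breeding populations
    (nuclear families, linkage disequilibrium among founder haplotypes,
    Poisson recombination, polygenic traits with skewed count observations),
    designs low-density SNP panels by masking evenly spaced marker subsets,
    imputes masked offspring genotypes with pedigree haplotype phasing plus
    an inheritance-origin hidden Markov model, and evaluates the downstream
    value of imputed genotypes for genomic selection: VanRaden genomic and
    pedigree numerator relationship matrices, the animal model solved via
    mixed-model equations with EM-REML variance components, and fivefold
    cross-validated prediction accuracy compared across pedigree BLUP and
    GBLUP on true, imputed, and low-density genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
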