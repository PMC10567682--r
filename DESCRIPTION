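Package: popkdr
Title: Population Structure and kdr Resistance Haplotypes from
    Microsatellite and SNP Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale population-genetic analysis of Aedes aegypti
    insecticide-resistance surveys. Decomposes tri-locus kdr (knockdown
    resistance) genotypes at Na_V sites 410/1016/1534 into haplotype pairs
    and estimates allele and genotype-class frequencies with equal-split or
    EM apportioning of ambiguous genotypes. Computes microsatellite
    diversity statistics (Na, Ne, Ho, He, unbiased He, private alleles,
    rarefied allelic richness, Fis), Hardy-Weinberg exact tests under
    Levene's conditional distribution, genotypic linkage-disequilibrium
    permutation tests with Bonferroni correction, a Brookfield null-allele
    estimator, Weir-Cockerham pairwise Fst with permutation significance
    and island-model Nm, two-level AMOVA, haversine distances and Mantel
    isolation-by-distance tests, Bayesian admixture clustering by Gibbs
    sampling with Evanno delta-K model selection and replicate-run
    alignment, and discriminant analysis of principal components (DAPC).
    Includes a Balding-Nichols synthetic-data generator emulating a
    six-population transect sampling design, and GENEPOP text I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
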