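Package: damline
Title: Dam-Line Proportion Estimation for Three-Way Crossbred Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the dam-line composition of three-way crossbred [A(BC)]
    animals from SNP genotypes. Implements sire-adjusted linear regression on
    line-specific allele frequencies, supervised maximum-likelihood admixture
    via an EM algorithm, and genomic-relationship estimators based on the
    maternal grandparents, together with breed-origin-of-alleles counting,
    constraint-enforcing post-processing, windowed LD pruning, Weir-Cockerham
    F_ST, evaluation metrics, the theoretical distribution of grandparental
    genome sharing, and a forward-in-time crossbreeding simulator with
    per-allele line-of-origin tracking that supplies a gold standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
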