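Package: dispersr
Title: Marker-Contrast Inference of Sex-Biased Dispersal from mtDNA and
    Microsatellite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for contrasting population structure between maternally
    inherited mitochondrial sequence data and biparentally inherited
    microsatellite genotypes to infer sex-biased dispersal. Implements
    haplotype collapsing with Nei diversity indices and their sampling
    variances, median-joining haplotype networks, Weir-Cockerham
    F-statistics and AMOVA Phi-ST with permutation tests, an exact
    Hardy-Weinberg Markov chain test, linkage-disequilibrium permutation
    tests, allele-randomization and locus-bootstrap diagnostics for null
    alleles, population monophyly checks on genealogies, Spearman Mantel
    correlation between marker classes, Bayes-factor ranking of migration
    models, and a forward-time two-sex metapopulation simulator for
    validating the whole pipeline under known sex-specific migration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
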