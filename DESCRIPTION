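Package: gaga
Title: Model-Free Detection of Fine-Scale Genetic Population Substructure
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fine-scale genetic population substructure from diploid
    biallelic SNP genotypes without a demographic model. Computes the T1
    pairwise genotype similarity and its distance D = 1 - T1, transforms D into
    the V matrix (the per-pair variance of the difference between the two
    individuals' distance profiles to all other individuals, which cancels
    within-population variation), decomposes either matrix with AMOVA, and
    searches the space of individual partitions with a genetic algorithm that
    maximizes the among-population sum of squares. Includes evaluation
    statistics (best-overall-match percentage, Cramer's V, informativeness for
    assignment), classical multidimensional scaling with Cailliez correction
    plus Gaussian-mixture clustering, and simulators (additive graph model,
    2-D stepping-stone, sequential-split, Hardy-Weinberg and Balding-Nichols
    genotypes) for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    mclust,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
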