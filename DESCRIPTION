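Package: coexmeth
Title: Differential Gene Coexpression Networks and DNA Methylation Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds weighted gene coexpression networks in a reference
    condition (soft-threshold selection by scale-free fit, unsigned
    adjacency, topological overlap, dynamic hybrid tree cut, module
    eigengenes and merging), tests module preservation in a second
    condition with a permutation panel of density and connectivity
    statistics (Z_density, Z_connectivity, Z_summary, medianRank), and
    integrates whole-genome bisulfite data: CpG coverage filtering,
    per-cytosine binomial logistic-regression tests of differential
    methylation, genomic region assignment, per-gene methylation levels,
    and distribution/regression links between methylation and network
    topology. Includes a synthetic-data generator with planted modules
    and planted differentially methylated cytosines for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    mclust,
    jsonlite
Config/testthat/edition: 3
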