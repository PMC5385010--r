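Package: sedipart
Title: Vertical Partitioning of Sediment Microbiome Beta-Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Community statistics for depth-stratified sediment microbiome
    surveys: Jaccard-family partitioning of beta-diversity into taxonomic
    replacement and richness-difference components, local and species
    contributions to beta-diversity (LCBD/SCBD) with permutation nulls,
    coverage-normalized Hill diversities, fuzzy set ordination of community
    components against environmental gradients, UPGMA horizon clustering,
    exponential DNA-decay modelling, and a depth-profile community simulator
    implementing the competing nested-burial and niche-replacement models of
    vertical sediment community structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
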