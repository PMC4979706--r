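Package: foxscape
Title: Landscape Genetics of Introduced Red Fox Metapopulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for landscape genetics of invasive red fox
    metapopulations typed at microsatellite and mitochondrial markers.
    Provides diversity and differentiation statistics (gene diversity,
    Weir-Cockerham theta, Nei's D_A, sex-biased gene-flow ratios),
    linkage-disequilibrium effective population size, heterozygote-excess
    bottleneck tests under IAM/SMM/TPM mutation models, neighbor-joining
    trees with locus bootstrap, principal coordinates of genotypic
    distances, Structure-style Bayesian admixture clustering with cluster
    profiles across K and migrant classification, model-free distance-decay
    residual surfaces, circuit-theory resistance distances, Mantel and
    partial Mantel tests, and a forward-time metapopulation simulator with
    founder effects and resistance-shaped sex-biased migration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    Matrix,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
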