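Package: urobiome
Title: Profiling Low-Biomass Genitourinary Microbiomes with Negative-Control Decontamination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of 16S rRNA amplicon surveys of low-biomass
    genitourinary specimens. Implements multilevel contaminant removal against
    sequencing negative controls (prevalence testing, negative-control read
    fraction and index-hopping/cross-talk filters), rarefaction and core
    microbiota profiling, alpha and beta diversity (Shannon, Faith's
    phylogenetic diversity, Bray-Curtis, unweighted UniFrac), urotype discovery
    by Ward clustering with Calinski-Harabasz and silhouette diagnostics,
    genus co-occurrence networks with keystone detection, gender and age cohort
    comparisons, and a sequencing-depth and sample-size sensitivity design
    tool. Ships a synthetic cohort generator with planted ground truth
    (contaminants, cross-talk artifacts, urotypes, a co-abundant genus trio)
    so every stage is testable without access to a real cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    mclust,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
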