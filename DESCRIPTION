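Package: cagdyn
Title: Co-Abundance Group Dynamics in Longitudinal Microbiota Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal 16S rRNA gene OTU-table
    analysis of two-group intervention studies with repeated sampling per
    subject. Covers rarefaction to a common depth, alpha diversity
    (observed OTUs and Shannon index averaged over repeated rarefactions),
    Bray-Curtis ordination with PerMANOVA and MANOVA on leading principal
    coordinates, random-forest discrimination with permutation-importance
    (mean decrease in accuracy) key-OTU selection and leave-one-out error,
    within-subject repeated-observations correlations, Ward clustering with
    sequential PerMANOVA tree-cutting into co-abundance groups (CAGs),
    co-abundance network export, and CAG temporal-dynamics detection with a
    log2-fold-change onset rule and Kruskal-Wallis/Dunn baseline tests. A
    Dirichlet-multinomial simulator generates longitudinal count tables
    with planted CAGs, differential OTUs and trajectories so every stage
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    randomForest,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
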