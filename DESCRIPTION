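Package: dmftmicro
Title: Oral Microbiota Dynamics Along the DMFT Caries Severity Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing salivary 16S amplicon communities along
    the DMFT (decayed/missing/filled teeth) caries severity index: sample
    depth filtering and taxonomic aggregation of feature tables, alpha and
    beta diversity (Bray-Curtis, Jensen-Shannon, weighted and unweighted
    UniFrac) with principal coordinate analysis and PERMANOVA, pan/core/
    accessory microbiota partitioning per severity category, Spearman
    co-occurrence networks with Benjamini-Hochberg FDR edge significance and
    a network entropy statistic, leave-one-genus-out ordination-variance
    influence analysis, and per-category quasi-Poisson models of microbial
    biomass. Includes a Dirichlet-multinomial cohort simulator with planted
    core/accessory structure and latent-factor correlations so every stage
    is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
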