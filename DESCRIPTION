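Package: crcmir
Title: MicroRNA-Based Molecular Subtyping and Regulatory-Network Target
    Prioritization for Colorectal Tumors
Version: 0.1.0
Authors@R:
    person("crcmir", "authors", email = "crcmir@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for unsupervised molecular subtyping of
    colorectal tumors from microRNA expression profiles and for downstream
    prioritization of miRNA-mRNA regulatory interactions.  Implements
    presence/count filtering, quantile normalization and median centering;
    hierarchical clustering with centered-Pearson distance (average or Ward
    linkage); one-way ANOVA with Student-Newman-Keuls post hoc comparisons
    and Benjamini-Hochberg correction; sparse (L1) negative-regulation
    miRNA-target inference with permutation significance; bipartite
    regulatory-network construction with closeness/radiality centralities and
    EAGLE-style overlapping community detection; seed-site matching in 3'UTR
    sequences with in-silico mutagenesis; and the contingency statistics used
    for subtype association tables.  A synthetic-cohort generator with
    planted subtypes and planted repressive edges provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet,
    igraph,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
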