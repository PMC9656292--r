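# crcmir

MicroRNA-based molecular subtyping of colorectal tumors and
miRNA–mRNA regulatory-network target prioritization.

## What this package is for

Colorectal tumors fall into reproducible molecular subtypes (the Consensus
Molecular Subtypes, CMS), normally defined from mRNA profiles.  miRNA
profiles can recover the same structure with unsupervised clustering — and
because one miRNA represses many transcripts, pairing miRNA and mRNA
profiles from the same cohort lets you infer which repressive miR→target
interactions distinguish the subtypes and which targets deserve bench
validation.  `crcmir` implements that whole workflow as tested, reusable R
code for computational biologists who want to:

1. **Subtype** tumors by miRNA expression: presence filtering (detected in
   ≥ 90% of samples), quantile normalization, median centering, then
   hierarchical clustering of samples with the centered-Pearson distance
   *d(i,j) = 1 − r(i,j)* under average linkage (discovery configuration) or
   Ward linkage (count-data validation configuration), cut at *k* = 3.
2. **Test subtype associations** with the contingency machinery used in
   such studies: Pearson χ² (no continuity correction), Fisher's exact
   test, Kruskal–Wallis, and the Mantel–Haenszel linear-by-linear trend
   test (n − 1)·r².
3. **Find differential expression**: one-way ANOVA with
   Student–Newman–Keuls post hoc comparisons on the studentized range
   (Tukey–Kramer SE for unbalanced groups), Benjamini–Hochberg correction,
   and the joint rule *adjusted p < 0.05 and pairwise FC > 1.5* (FC =
   2^|Δmean| on log2 data); plus two-group pooled-variance t contrasts.
4. **Infer miR→target interactions** from expression: per-gene
   L1-penalized (lasso) regression of each transcript on its candidate
   miRNAs with a negative-regulation sign constraint, 5-fold CV penalty
   selection, and label-permutation significance
   p = (1 + #{|β\*| ≥ |β|}) / (n_perm + 1).
5. **Analyze the regulatory network**: bipartite miR–gene graph, largest
   connected component, closeness (n−1)/Σd and radiality
   Σ(Δ+1−d)/(n−1) centralities, EAGLE-style overlapping community
   detection by maximal-clique agglomeration, and the candidate rule
   "edges among the 20 most central nodes ∪ edges inside the most relevant
   community".
6. **Prioritize candidates** with precomputed evidence scores (WSP, LRS,
   prediction-algorithm counts), dropping database-validated pairs, and
   check target sites directly: the 7-mer seed-complement motif of a
   mature miRNA, exact site search in 3′UTR coordinates, and in-silico
   point mutagenesis.

Every stage is exercised against a **synthetic cohort generator** that
plants three miRNA subtypes (27/30/31 tumors + 19 normals, 176 miRNAs,
1722 genes, three signature blocks) and a set of repressive miR→gene edges
(one deliberately hub-like regulator), so recovery is measurable against
ground truth.

## Worked example

```r
library(crcmir)

cohort <- generate_cohort(cohort_spec(rng_seed = 1))
filt   <- presence_filter(cohort$mirna, fraction = 0.90)
mir    <- median_center(quantile_normalize(impute_undetected(filt$matrix)))

tumors   <- cohort$annotation$sample_id[cohort$annotation$tissue == "tumor"]
d        <- pearson_distance(mir, centered = TRUE)[tumors, tumors]
subtypes <- cut_k(cluster_samples(d, linkage = "average"), k = 3)
subtypes
#> <subtype_assignment> k=3: S1=27, S2=30, S3=31

adjusted_rand_index(subtypes$labels[tumors],
                    cohort$truth$subtype_of_sample[tumors])
#> [1] 1

# a printed-table association check: microsatellite status by subtype
msi <- rbind(MSS = c(24, 24, 31), MSI = c(3, 6, 0))
chi_square(msi)
#> statistic 6.675, df 2, p 0.036
```

The presence filter logs `174 of 176 features detected in >= 90% of
samples` for this seed; the three recovered clusters match the planted
subtype sizes 27/30/31 exactly (Adjusted Rand Index 1), and the χ² on the
2×3 microsatellite table reproduces the published p = 0.036.

An end-to-end run (simulate → preprocess → subtype → DE → interactions →
networks → candidates → associations, with a JSON manifest of seeds and
file checksums) is one call:

```r
run_all("out/", pipeline_config(rng_seed = 1))
```

or from the command line via the bundled launcher
(`inst/cli/crcmir`): `Rscript inst/cli/crcmir run-all --seed 1 --outdir out/`.

## Documentation

`vignettes/methods.Rmd` describes the statistical model of every stage,
the synthetic-data design and what a green test does and does not
establish, and the numerical/design decisions taken where the published
workflow leaves choices open.
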