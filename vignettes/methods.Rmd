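---
title: "Methods: miRNA subtyping and regulatory-network prioritization"
author: "crcmir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA subtyping and regulatory-network prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcmir)
options(crcmir.quiet = TRUE)
```

# Overview

`crcmir` reimplements, as a tested pipeline, a workflow for classifying
colorectal tumors into molecular subtypes from microRNA expression and for
prioritizing miRNA–mRNA repressive interactions from paired expression
profiles.  This vignette is the package's own account of the statistics
involved: the model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the underlying workflow left genuine
choices open.

# Preprocessing

**Presence filter.** Microarray platforms flag each measurement as
detected or not.  A feature is kept when detected in at least a fraction
`presence_fraction` (default 0.90) of samples; the boundary is inclusive
(a feature detected in exactly 90% of samples passes).  Empty cells and
`NA` strings in a TSV both map to "undetected" since exports differ.

**Imputation.** Quantile normalization needs complete columns.  Undetected
cells are imputed to the feature's minimum detected value — a conservative
floor consistent with "below detection", and logged.  This is our choice;
the source workflow is silent on it.

**Quantile normalization** forces every sample column to share the mean
order-statistic distribution.  Ties receive interpolated reference values.
Note a scale caveat that matters for synthetic benchmarks: with only ~100
features per column the procedure grids values onto ~100 ranks and can
destroy within-feature dose–response signal entirely (a feature whose rank
is constant becomes constant).  It is therefore applied to the miRNA
microarray intensities — its original role — and *not* to the mRNA panel,
which enters the pipeline as already-normalized log2 data.

**Median centering** subtracts each feature's median; it is idempotent and
preserves all within-feature differences, so fold changes are unaffected.

**Count filter** (for sequencing-style validation data): a feature is
dropped when it has fewer than `min_count` (10) counts in strictly more
than `max_low_fraction` (90%) of samples.  "More than" is strict: low in
exactly 90% keeps the feature.

**PCA outlier screen.** The source workflow excluded samples by visual
inspection of a 3D PCA.  We operationalize this as: project samples on the
first 3 principal components and flag those whose Euclidean distance from
the score centroid exceeds mean + k·sd of all distances (default k = 3,
configurable).  The rule reduces to the visual judgment in the obvious
cases and is deterministic.

# Subtyping

Samples are clustered on the **centered Pearson distance**
d(i,j) = 1 − r(i,j), r computed over features with profiles mean-centered
(the uncentered variant — correlation about zero, i.e. cosine similarity —
is available for data already centered per feature).  The distance lies in
[0, 2], is symmetric with a zero diagonal, and a zero-variance profile is
an error naming the offending sample.

Agglomeration is **average linkage** (UPGMA) for the discovery
configuration or **Ward** for the count-data configuration.  Ward on a
correlation-derived dissimilarity follows the common
"`ward.D2`-on-dissimilarity" contract: the dissimilarities are treated as
distances and squared internally.  Dendrogram leaves are ordered
deterministically (tighter subtree left, ties by smallest leaf index) so
snapshot tests are stable; the published figures came from a GUI whose
ordering is unstated.

`cut_k` removes the k − 1 highest merges and labels flat clusters S1, S2,
… by first-occurring sample.  k is fixed at 3 by configuration: the
source study chose three clusters by inspecting the tree, which we do not
automate.  Feature-side clustering (`order_features`) uses the same
machinery on feature rows for heatmap ordering and for reading off
contiguous signature blocks.

# Differential expression

Per feature, a one-way ANOVA F test across subtypes, then
**Student–Newman–Keuls** comparisons: group means are ranked and each pair
is tested with the studentized range at the span r of the pair in the
ranked order, q = |Δmean| / sqrt(MSE/2 · (1/nᵢ + 1/nⱼ)).  Classical SNK
assumes balanced groups; for the unbalanced cohort we use the Tukey–Kramer
standard error (equivalent to the harmonic-mean-n adaptation).
Non-significance propagates inward: a pair's reported p is the maximum raw
p over all ranked ranges enclosing it, so no pair can be called inside a
non-significant range.  `snk_significant` additionally gates on the global
test (the "protected" protocol), which enforces the consistency property
that no pairwise call survives a failed global test.

Global p-values are **Benjamini–Hochberg** adjusted across features
(step-up; own implementation, cross-checked against `p.adjust`).  The
selection rule is: adjusted global p < 0.05 **and** at least one pairwise
fold change > 1.5.  Whether the source applied the threshold to raw or
adjusted p is unstated; adjusted is the default, raw is a config switch
(`use_adjusted_global = FALSE`).  Fold change is computed on anti-logged
group means of log2 data (geometric-mean ratio), reported as a value ≥ 1
plus a direction sign — the standard convention for log-scale microarray
data; the source is silent here too.

Two-group contrasts (tumor vs normal, stroma vs epithelium) use the
equal-variance unpaired t-test with the same BH/FC machinery.

# Interaction inference

The source workflow used an external L1-regression tool whose exact
objective and significance device are not recoverable from its
description.  We therefore *reimplement the contract* rather than port the
tool, and say so prominently: per gene, an L1-penalized least-squares
regression of the gene profile on its candidate miRNAs (glmnet; penalty by
5-fold cross-validation with seeded, sample-id-keyed folds; ties on the
error path resolved toward stronger sparsity), followed by a hard sign
constraint — positive coefficients are clipped to zero, because the model
is repression.  A single candidate degenerates to OLS (the penalty-free
limit).  Quasi-binary gene profiles (≤ 5 distinct values, as quantile
normalization can produce on small panels) return zero coefficients: CV
folds can be degenerate there and such profiles carry no dose–response
signal.

**Permutation significance.** Each retained (negative) coefficient gets
p = (1 + #{|β\*| ≥ |β|}) / (n_perm + 1) over `n_perm` (default 199)
permutations of the miR profile's sample labels.  The permutation
statistic is the *marginal* OLS slope of gene on miR, not a lasso refit:
it is exchangeable under the null, boundary cases behave exactly (observed
slope 0 → p = 1; perfect anti-correlation with 999 permutations →
p = 1/1000), and it is cheap enough for hundreds of replicates per edge.
Edges with p < 0.05 survive.  Genes are processed independently with
per-gene seeds derived from the run seed and the gene id, so the edge set
is identical under any scheduling or input order; columns are canonicalized
by sample id so fold assignment never depends on column order.

**Candidate pairs.** In real use the tested pairs come from a putative
target table (sequence-based predictions); dense all-pairs mode exists for
small synthetic worlds.  The recovery benchmarks use a prior list of all
planted edges plus 5 decoy pairs per true edge (`benchmark_pairs`).  The
factor 5 was fixed a priori: enough decoys for precision to be meaningful,
small enough that the 10-seed benchmark stays inside its time budget.  The
dense 176 × 1722 cross product (~300k fits per seed) is not used in the
benchmark — the original analysis also screened a precomputed putative-pair
table, not the cross product.

# Network analysis

Significant interactions among a subtype's differentially expressed genes
form an undirected **bipartite** miR–gene graph; only the largest
connected component is retained (ties by node count, then lexicographic
smallest member).  Centralities, with unit edge lengths and geodesic
distances d:

* closeness(v) = (n − 1) / Σ_w d(v, w)
* radiality(v) = Σ_w (Δ + 1 − d(v, w)) / (n − 1), Δ the diameter.

Both are verified against a brute-force BFS oracle in the tests.  On
vertex-transitive graphs the two rank nodes identically, the exact form of
the empirical observation that the two measures select the same top genes.

**EAGLE-style communities.** Maximal cliques of size ≥
`clique_size_threshold` (3) seed communities; nodes outside all such
cliques join as singletons; the pair of communities with the largest
overlap fraction |A∩B|/min(|A|,|B|) is merged until no pair reaches
`merge_threshold` (0.5 — the original algorithm's stopping parameter is
not recoverable from the workflow description, so this default is ours);
communities below `complex_size_threshold` (2) are discarded.  A bipartite
graph is triangle-free, so its maximal cliques are bare edges and direct
clique agglomeration degenerates — a point the original analysis did not
address.  Default behaviour on regulatory networks is therefore
`mode = "projection"`: the graph is augmented with its two one-mode
projections (genes sharing a regulator, miRs sharing a target), which
restores cliques (a miR plus its targets is one) while communities remain
subsets of real nodes.  The raw `mode = "bipartite"` is available for
completeness.

**Candidate selection** is the union of (a) edges with both endpoints in
the top-central set — the intersection of the top-20 lists by closeness
and by radiality, padded back to 20 by closeness rank; ties broken by
closeness rank, then degree, then id — and (b) all edges inside the most
relevant community.  "Most relevant" is operationalized as highest mean
member closeness (ties to the larger community); the source workflow does
not define it.

# Candidate prioritization and seed sites

Candidate edges carry precomputed evidence columns: WSP and LRS combined
prediction scores and the number of supporting prediction algorithms
(0–5).  These scores are consumed, not recomputed — their definitions live
in the annotation source.  Edges already validated in interaction
databases are removed; the rest are ordered by the descending sum of the
three within-list ranks (equal weights — our operationalization of
"annotated and scored"; the weights are exposed), ties by the target
gene's network closeness.

The sequence layer implements canonical 7-mer seed matching only: the site
motif is the reverse complement of mature-miRNA nucleotides 2–8 written as
DNA (for mature miR-30b-5p, `UGUAAACAUCCUACACUCAGCU`, this is `TGTTTAC`);
`find_sites` reports exact occurrences in the 3′UTR's own 1-based
coordinate frame (sequence fragments carry an `origin`); and
`apply_substitutions` applies `<ref><pos><alt>` point changes, refusing any
substitution whose reference base does not match — the guard that catches
coordinate-frame errors.  Wobble pairs, 8-mer/offset site classes and
thermodynamic duplex models are deliberately out of scope.  The published
mutagenesis oligonucleotide does not visibly align with a wild-type site
at the printed coordinates under a naive offset, so site-destruction tests
run on constructed fixtures (labelled `synthetic`) built to the printed
coordinates instead.

# Association statistics

Pearson χ² without continuity correction (zero margins are an error);
Fisher's exact test in the standard two-sided "sum of no-more-probable
tables" convention, refused beyond ~10×10 or n ≈ 200 where enumeration is
not exact; Kruskal–Wallis with tie correction; Mantel–Haenszel
linear-by-linear trend (n − 1)·r² on ordinal scores (default 1..r), which
— unlike plain χ² — is order-sensitive.  Published "0.000" p-values are
treated as the bound p < 0.0005 and asserted as bounds only.
Subtype-association tables include "NA"/"Unclassified" rows as ordinary
categories; this convention is what reproduces the published 5×3 CMS-table
p = 0.001.  One caveat verified empirically: within the exact test's
n ≤ 200 budget, Fisher and χ² p-values only agree closely (< 0.02) on
association-bearing tables; near the null the exact test remains up to
~0.1 more conservative at these counts.

# The synthetic cohort: what it emulates, and what it does not

`cohort_spec()` defaults state the world the tests live in:

| parameter | default | rationale |
|---|---|---|
| tumors per subtype | 27/30/31 | published subtype sizes (the table is taken as authoritative over a conflicting passage of running text) |
| normals | 19 | published normal-colon count |
| miRNAs / genes | 176 / 1722 | published expressed-miR and gene-panel counts |
| signature blocks | 23/21/29 miRs | published heatmap cluster sizes; geometry: block A up in S2 / down in S1, block B down in S3, block C up in S3 |
| block shift | 1.0 log2 | free parameter (effect sizes unpublished); 2× the noise sd, a separation a microarray study would call clear |
| edge effect β | 0.8 | free parameter; log2-per-log2 repression slope of clearly detectable but not trivial strength |
| noise sd | 0.5 log2 | typical residual spread for log-intensity microarray data |
| missing rate | 0.05 | enough to exercise detection flags without starving the presence filter |
| planted edges | 30, ≤ 3 per gene, one hub miR with ~20% of edges | real miR target-count distributions are heavy-tailed; the hub anchors the network-stage recovery tests |

Per-feature baselines are drawn from N(8, 2²) so median centering is
non-trivial.  Repression is linear in log2 space, matching the
sign-constrained linear inference model; regulation also applies in
normals (subtype shifts do not).  The generator does **not** emulate
probe-level artifacts, batch effects, count overdispersion beyond what the
count filter needs, or nonlinear regulation.  Consequently a green
recovery test establishes that the pipeline's machinery is correct and
calibrated on data obeying its own model assumptions — it does not
establish that the published cohort-level counts (numbers of significant
interactions, DE genes per subtype, and so on) are reproducible; those
depend on the original arrays and database snapshots, which are out of
scope.  Two visible consequences of the stated world: regulators are drawn
mostly outside the signature blocks, so subtype-restricted DE gene lists —
and hence the per-subtype networks — are far sparser than the published
ones; and the noise-free corr(miR, target) = −1 limit holds exactly only
when the planted regulator carries between-subtype variance.

# Numerical choices and degenerate inputs

Distances are clipped at 0 against floating-point noise and symmetrized
exactly.  `cutree` tie behaviour (merge-index order) is inherited and
logged.  Zero-variance profiles: error in centered Pearson distance (named
sample), p = 1 in permutation significance, error in ANOVA when a whole
group has no variance anywhere.  Empty p-vector → empty BH result.
Singleton networks score 0 on both centralities.  A degenerate
(zero-variance) matrix yields an empty PCA outlier list.  All stochastic
steps (generator, CV folds, permutations) run under explicit seeds;
per-gene seeds are derived from the run seed and the gene id so results
are independent of gene order and scheduling.

# Known limitations

* The interaction step is a contract-preserving reimplementation of an
  external tool, not a port; absolute interaction counts will differ.
* Exact Fisher is limited to small tables by design.
* EAGLE's merge-stop threshold and the "most relevant cluster" rule are
  our operationalizations; both are parameters.
* Seed matching is exact-7-mer only.
* No survival analysis, no batch correction, no probe-level processing.
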