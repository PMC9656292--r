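#' Synthetic cohort specification
#'
#' Describes the simulated paired miRNA/mRNA cohort.  The defaults emulate
#' the discovery cohort scale: 88 tumors split into three planted subtypes
#' of 27/30/31 samples plus 19 normal colon samples, 176 expressed miRNAs
#' and 1722 genes.  Three disjoint miRNA signature blocks reproduce the
#' qualitative heatmap geometry of the published subtypes: block A is
#' shifted up in S2 and down in S1, block B down in S3, block C up in S3
#' (block sizes 23/21/29, matching the printed cluster sizes).  A set of
#' planted repressive miR->gene edges (log2-linear, slope `-edge_effect`)
#' provides ground truth for interaction inference.
#'
#' @param n_tumors_per_subtype integer vector of tumor counts per subtype.
#' @param n_normals number of normal samples (no subtype shifts).
#' @param n_mirs,n_genes feature counts.
#' @param block_sizes sizes of the three signature blocks (up-in-S2/down-in-S1,
#'   down-in-S3, up-in-S3); `NULL` scales the 23/21/29 pattern to `n_mirs`.
#' @param block_shift magnitude of the subtype shift, log2 units.
#' @param edge_effect planted repression slope beta (> 0; genes move by
#'   `-beta` per log2 unit of regulator).
#' @param noise_sd Gaussian noise standard deviation, log2 units.
#' @param missing_rate fraction of cells whose detection flag is dropped.
#' @param n_edges number of planted miR->gene edges.
#' @param max_regulators_per_gene cap on planted regulators per gene.
#' @param rng_seed integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tumors_per_subtype = c(27L, 30L, 31L),
                        n_normals = 19L,
                        n_mirs = 176L,
                        n_genes = 1722L,
                        block_sizes = NULL,
                        block_shift = 1.0,
                        edge_effect = 0.8,
                        noise_sd = 0.5,
                        missing_rate = 0.05,
                        n_edges = 30L,
                        max_regulators_per_gene = 3L,
                        rng_seed = 1L) {
  if (is.null(block_sizes))
    block_sizes <- pmax(1L, as.integer(round(n_mirs * c(23, 21, 29) / 176)))
  spec <- list(n_tumors_per_subtype = as.integer(n_tumors_per_subtype),
               n_normals = as.integer(n_normals),
               n_mirs = as.integer(n_mirs),
               n_genes = as.integer(n_genes),
               block_sizes = as.integer(block_sizes),
               block_shift = block_shift,
               edge_effect = edge_effect,
               noise_sd = noise_sd,
               missing_rate = missing_rate,
               n_edges = as.integer(n_edges),
               max_regulators_per_gene = as.integer(max_regulators_per_gene),
               rng_seed = as.integer(rng_seed))
  if (any(spec$n_tumors_per_subtype < 2) || spec$n_normals < 2)
    stopf("each sample group needs at least 2 samples")
  if (spec$noise_sd <= 0) stopf("noise_sd must be > 0")
  if (spec$edge_effect <= 0) stopf("edge_effect must be > 0 (repression slope)")
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stopf("missing_rate must be in [0, 1)")
  if (spec$n_edges > spec$n_mirs * spec$n_genes)
    stopf("more edges requested (%d) than miR x gene pairs (%d)",
          spec$n_edges, spec$n_mirs * spec$n_genes)
  if (length(spec$block_sizes) != 3 || sum(spec$block_sizes) > spec$n_mirs)
    stopf("block_sizes must be 3 values summing to at most n_mirs")
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic paired miRNA/mRNA cohort
#'
#' Simulates log2-scale expression.  Per-feature baselines are drawn from a
#' wide Gaussian (mean 8, sd 2) so that median centering is non-trivial.
#' Tumor miRNA values are baseline + subtype block shift + noise; each gene
#' carrying planted edges is baseline - sum(beta * miR value) + noise; genes
#' without edges are baseline + noise.  Normal samples have all subtype
#' shifts at zero (regulation still applies).  Detection flags are dropped
#' uniformly at random at `missing_rate`.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `mirna` and `mrna` ([expression_matrix()]s),
#'   `annotation` (data.frame) and `truth` (list of class `synthetic_truth`
#'   with `subtype_of_sample`, `signature_blocks`, `true_edges`,
#'   `normal_samples`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$rng_seed)
  n_sub <- length(spec$n_tumors_per_subtype)
  subtype_labels <- paste0("S", seq_len(n_sub))
  n_tumors <- sum(spec$n_tumors_per_subtype)
  tumor_ids <- sprintf("T%03d", seq_len(n_tumors))
  normal_ids <- sprintf("N%03d", seq_len(spec$n_normals))
  samples <- c(tumor_ids, normal_ids)
  subtype <- rep(subtype_labels, times = spec$n_tumors_per_subtype)
  names(subtype) <- tumor_ids

  mir_ids <- sprintf("miR-%03d", seq_len(spec$n_mirs))
  gene_ids <- sprintf("gene-%04d", seq_len(spec$n_genes))

  bs <- spec$block_sizes
  block_a <- mir_ids[seq_len(bs[1])]
  block_b <- mir_ids[bs[1] + seq_len(bs[2])]
  block_c <- mir_ids[bs[1] + bs[2] + seq_len(bs[3])]
  # signed shift per (miR block, subtype): cluster-A analog up in S2, down in
  # S1; cluster-B analog down in S3; cluster-C analog up in S3
  shift <- matrix(0, nrow = spec$n_mirs, ncol = n_sub,
                  dimnames = list(mir_ids, subtype_labels))
  shift[block_a, "S1"] <- -spec$block_shift
  shift[block_a, "S2"] <- +spec$block_shift
  shift[block_b, "S3"] <- -spec$block_shift
  shift[block_c, "S3"] <- +spec$block_shift

  n_samples <- length(samples)
  mir_base <- stats::rnorm(spec$n_mirs, mean = 8, sd = 2)
  mir_vals <- matrix(mir_base, nrow = spec$n_mirs, ncol = n_samples,
                     dimnames = list(mir_ids, samples))
  for (s in seq_len(n_sub)) {
    cols <- tumor_ids[subtype == subtype_labels[s]]
    mir_vals[, cols] <- mir_vals[, cols] + shift[, s]
  }
  mir_vals <- mir_vals +
    matrix(stats::rnorm(spec$n_mirs * n_samples, sd = spec$noise_sd),
           nrow = spec$n_mirs)

  # planted edges: unique (miR, gene) pairs, at most max_regulators_per_gene
  # per gene. Regulator multiplicity is deliberately heavy-tailed: one
  # designated hub miR carries ~20% of the edges (miR target counts in real
  # networks are skewed; the hub anchors the network-stage recovery tests),
  # the rest are drawn uniformly.
  edges <- data.frame(mir = character(0), gene = character(0), beta = numeric(0))
  if (spec$n_edges > 0) {
    max_slots <- spec$n_genes * spec$max_regulators_per_gene
    if (spec$n_edges > max_slots)
      stopf("n_edges exceeds n_genes * max_regulators_per_gene")
    hub <- sample(mir_ids, 1)
    n_hub <- min(spec$n_edges, spec$n_genes, max(3L, round(0.2 * spec$n_edges)))
    hub_genes <- sample(gene_ids, n_hub)
    n_rest <- spec$n_edges - n_hub
    gene_pool <- rep(gene_ids, each = spec$max_regulators_per_gene)
    slots <- sample(length(gene_pool), n_rest)
    e_gene <- gene_pool[slots]
    repeat {
      e_mir <- if (length(mir_ids) > 1)
        sample(setdiff(mir_ids, hub), n_rest, replace = TRUE)
      else rep(hub, n_rest)
      if (!anyDuplicated(paste(e_mir, e_gene))) break
    }
    edges <- data.frame(mir = c(rep(hub, n_hub), e_mir),
                        gene = c(hub_genes, e_gene),
                        beta = spec$edge_effect, stringsAsFactors = FALSE)
    # respect the per-gene regulator cap across hub and uniform draws
    over <- names(which(table(edges$gene) > spec$max_regulators_per_gene))
    for (g in over) {
      idx <- which(edges$gene == g)
      drop <- idx[-seq_len(spec$max_regulators_per_gene)]
      repl <- sample(setdiff(gene_ids, edges$gene), length(drop))
      edges$gene[drop] <- repl
    }
  }

  gene_base <- stats::rnorm(spec$n_genes, mean = 8, sd = 2)
  gene_vals <- matrix(gene_base, nrow = spec$n_genes, ncol = n_samples,
                      dimnames = list(gene_ids, samples))
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      g <- edges$gene[i]
      gene_vals[g, ] <- gene_vals[g, ] - edges$beta[i] * mir_vals[edges$mir[i], ]
    }
  }
  gene_vals <- gene_vals +
    matrix(stats::rnorm(spec$n_genes * n_samples, sd = spec$noise_sd),
           nrow = spec$n_genes)

  drop_mask <- function(nr, nc) {
    matrix(stats::runif(nr * nc) >= spec$missing_rate, nrow = nr)
  }
  mir_det <- drop_mask(spec$n_mirs, n_samples)
  gene_det <- drop_mask(spec$n_genes, n_samples)
  mir_na <- mir_vals; mir_na[!mir_det] <- NA_real_
  gene_na <- gene_vals; gene_na[!gene_det] <- NA_real_
  dimnames(mir_det) <- dimnames(mir_vals)
  dimnames(gene_det) <- dimnames(gene_vals)

  annotation <- data.frame(
    sample_id = samples,
    tissue = c(rep("tumor", n_tumors), rep("normal", spec$n_normals)),
    mrna_subtype = c(subtype, rep(NA_character_, spec$n_normals)),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    subtype_of_sample = subtype,
    signature_blocks = list(
      up_S2_down_S1 = block_a,
      down_S3 = block_b,
      up_S3 = block_c),
    true_edges = edges,
    normal_samples = normal_ids), class = "synthetic_truth")

  stage_log("simulate", "%d tumors (%s) + %d normals; %d miRs, %d genes, %d planted edges",
            n_tumors, paste(spec$n_tumors_per_subtype, collapse = "/"),
            spec$n_normals, spec$n_mirs, spec$n_genes, nrow(edges))

  list(mirna = expression_matrix(mir_na, mir_det, "log2"),
       mrna = expression_matrix(gene_na, gene_det, "log2"),
       annotation = annotation,
       truth = truth)
}

#' Cross-tabulate two label vectors, optionally with planted association
#'
#' With `association_strength = 0` the two label vectors are drawn (or taken)
#' independently; a positive strength copies `labels_a` into `labels_b` for
#' that fraction of positions (when `labels_b` has the same level set),
#' planting a diagonal association.  Mainly a fixture factory for the
#' contingency statistics.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param association_strength fraction in \[0, 1\] of positions where the
#'   `labels_b` entry is overwritten with the `labels_a` entry.
#' @return A contingency table (class `table`) of counts.
#' @export
generate_contingency <- function(labels_a, labels_b, association_strength = 0) {
  if (length(labels_a) != length(labels_b))
    stopf("label vectors differ in length (%d vs %d)",
          length(labels_a), length(labels_b))
  if (association_strength < 0 || association_strength > 1)
    stopf("association_strength must be in [0, 1]")
  if (association_strength > 0) {
    n <- length(labels_a)
    take <- seq_len(floor(association_strength * n))
    labels_b[take] <- labels_a[take]
  }
  table(labels_a, labels_b)
}
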