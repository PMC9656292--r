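#' Build the candidate miR-gene pair list
#'
#' With a prior pair list (the usual mode: a putative-target table from
#' sequence-based predictions), pairs referencing features absent from the
#' supplied id sets are dropped with a warning.  Without a prior, all
#' miR x gene pairs are generated (dense mode, intended for synthetic
#' benchmarks).
#'
#' @param mir_ids,gene_ids available feature ids.
#' @param prior_pairs optional data.frame with columns `mir`, `gene`.
#' @return A data.frame with columns `mir`, `gene` (unique pairs).
#' @export
build_candidate_pairs <- function(mir_ids, gene_ids, prior_pairs = NULL) {
  if (is.null(prior_pairs)) {
    out <- expand.grid(mir = mir_ids, gene = gene_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    if (!all(c("mir", "gene") %in% names(prior_pairs)))
      stopf("prior_pairs needs 'mir' and 'gene' columns")
    known <- prior_pairs$mir %in% mir_ids & prior_pairs$gene %in% gene_ids
    if (any(!known)) {
      warning(sprintf("dropping %d prior pair(s) with unknown feature ids",
                      sum(!known)), call. = FALSE)
      stage_log("interactions", "dropped %d of %d prior pairs (unknown ids)",
                sum(!known), nrow(prior_pairs))
    }
    out <- prior_pairs[known, c("mir", "gene")]
  }
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' L1-penalized fit of one gene on its candidate miRNAs
#'
#' Least-squares regression of the gene profile on the candidate miR
#' profiles with a lasso penalty; the penalty is chosen by 5-fold
#' cross-validation (deterministic folds under `rng_seed`), with ties on
#' the error path broken toward stronger sparsity (`lambda.1se`-style
#' selection is not used; the rule is: smallest CV error, then largest
#' lambda among ties).  Positive coefficients are clipped to zero after the
#' fit -- the negative-regulation contract: miRNAs repress their targets.
#' A single candidate degenerates to ordinary least squares (the
#' penalty-to-zero limit), sign-clipped the same way.
#'
#' @param gene_profile numeric vector (log2 expression across samples).
#' @param mir_profiles matrix, samples in rows, candidate miRs in columns.
#' @param rng_seed integer seed controlling CV fold assignment.
#' @param nfolds folds for cross-validation (default 5).
#' @return Named coefficient vector (one per candidate; <= 0 everywhere).
#' @export
fit_gene_lasso <- function(gene_profile, mir_profiles, rng_seed = 1L,
                           nfolds = 5L) {
  x <- as.matrix(mir_profiles)
  n <- length(gene_profile)
  if (nrow(x) != n) stopf("profile lengths differ")
  if (n < 2) stopf("need at least 2 samples")
  if (stats::var(gene_profile) < 1e-12)  # (near-)constant target: nothing to explain
    return(stats::setNames(rep(0, ncol(x)), colnames(x)))
  if (ncol(x) == 1) {
    b <- ols_slope(x[, 1], gene_profile)
    coefs <- stats::setNames(b, colnames(x))
  } else {
    if (length(unique(gene_profile)) <= nfolds)
      # too few distinct values: CV folds can be constant in y, and such a
      # quasi-binary profile carries no usable dose-response signal anyway
      return(stats::setNames(rep(0, ncol(x)), colnames(x)))
    set.seed(rng_seed)
    foldid <- sample(rep_len(seq_len(nfolds), n))
    cv <- glmnet::cv.glmnet(x, gene_profile, alpha = 1, foldid = foldid,
                            standardize = TRUE)
    lam <- max(cv$lambda[cv$cvm <= min(cv$cvm) + 1e-12])  # sparser on ties
    coefs <- as.numeric(stats::coef(cv$glmnet.fit, s = lam))[-1]
    names(coefs) <- colnames(x)
  }
  pmin(coefs, 0)
}

# slope of y ~ x (OLS); 0 for a constant x
ols_slope <- function(x, y) {
  vx <- stats::var(x)
  if (is.na(vx) || vx == 0) return(0)
  stats::cov(x, y) / vx
}

#' Permutation significance of one miR-gene association
#'
#' Permutes the sample labels of the miR profile and compares the absolute
#' marginal regression slope of gene on miR against its permutation
#' distribution: p = (1 + #\{|slope_perm| >= |slope_obs|\}) / (n_perm + 1).
#' The marginal slope (not the multivariate lasso coefficient) is the
#' permutation statistic: it is exchangeable under the label permutation
#' and cheap enough for hundreds of replicates per edge.  A constant
#' profile yields p = 1.
#'
#' @param gene_profile,mir_profile numeric vectors over matched samples.
#' @param n_perm number of permutations (>= 99).
#' @param rng_seed integer seed.
#' @return A p-value in (0, 1\].
#' @export
permutation_significance <- function(gene_profile, mir_profile,
                                     n_perm = 199L, rng_seed = 1L) {
  if (n_perm < 99) stopf("n_perm must be >= 99")
  n <- length(gene_profile)
  if (length(mir_profile) != n) stopf("profile lengths differ")
  vx <- stats::var(mir_profile)
  if (is.na(vx) || vx == 0 || stats::var(gene_profile) == 0) return(1)
  obs <- abs(ols_slope(mir_profile, gene_profile))
  xc <- mir_profile - mean(mir_profile)
  yc <- gene_profile - mean(gene_profile)
  denom <- sum(xc^2)
  set.seed(rng_seed)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    abs(sum(xc[sample.int(n)] * yc) / denom)
  }, numeric(1))
  (1 + sum(perm_stats >= obs - 1e-12)) / (n_perm + 1)
}

#' Infer the miRNA-target interaction table
#'
#' Per gene: lasso fit on the gene's candidate miRs ([fit_gene_lasso()]);
#' every retained (strictly negative) coefficient is then assigned a
#' label-permutation p ([permutation_significance()]); edges with p below
#' `p_threshold` survive.  Genes are processed independently with
#' deterministic per-gene seeds derived from `rng_seed`, so results do not
#' depend on scheduling or gene order.
#'
#' @param mirna,mrna [expression_matrix()]s with matched sample columns.
#' @param pairs candidate pairs from [build_candidate_pairs()].
#' @param p_threshold permutation-p cutoff (default 0.05).
#' @param n_perm permutations per edge (default 199).
#' @param rng_seed integer seed.
#' @param de_context optional named list subtype -> character vector of DE
#'   genes; each record is annotated with the subtypes whose DE list
#'   contains its gene.
#' @return A data.frame of class `interaction_table`: `mir`, `gene`,
#'   `coefficient` (< 0), `perm_p`, `subtype_context` (comma-separated,
#'   possibly empty).
#' @export
infer_interactions <- function(mirna, mrna, pairs, p_threshold = 0.05,
                               n_perm = 199L, rng_seed = 1L,
                               de_context = NULL) {
  if (!identical(sample_ids(mirna), sample_ids(mrna))) {
    mism <- union(setdiff(sample_ids(mirna), sample_ids(mrna)),
                  setdiff(sample_ids(mrna), sample_ids(mirna)))
    if (length(mism) > 0)
      stopf("sample mismatch between matrices: %s", paste(mism, collapse = ", "))
    # same set, different order: align mRNA columns to the miRNA order
    mrna <- em_subset(mrna, samples = sample_ids(mirna))
  }
  # canonicalize the column order so CV folds and permutations depend on
  # sample identities, never on the incoming column order
  canon <- order(sample_ids(mirna))
  mirna <- em_subset(mirna, samples = canon)
  mrna <- em_subset(mrna, samples = canon)
  miss_m <- setdiff(unique(pairs$mir), feature_ids(mirna))
  miss_g <- setdiff(unique(pairs$gene), feature_ids(mrna))
  if (length(miss_m) > 0 || length(miss_g) > 0)
    stopf("pairs reference unknown features: %s",
          paste(c(miss_m, miss_g), collapse = ", "))
  genes <- sort(unique(pairs$gene))
  mirv <- t(mirna$values)   # samples x miRs
  mrv <- mrna$values
  records <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    cands <- sort(unique(pairs$mir[pairs$gene == g]))
    # stable per-gene seed independent of gene order / scheduling
    gene_seed <- (rng_seed + 7919L * (sum(utf8ToInt(g)) %% 10007L)) %% .Machine$integer.max
    coefs <- fit_gene_lasso(mrv[g, ], mirv[, cands, drop = FALSE],
                            rng_seed = gene_seed)
    kept <- names(coefs)[coefs < 0]
    if (length(kept) == 0) next
    rec <- lapply(kept, function(mm) {
      p <- permutation_significance(mrv[g, ], mirv[, mm],
                                    n_perm = n_perm,
                                    rng_seed = gene_seed + match(mm, cands))
      data.frame(mir = mm, gene = g, coefficient = unname(coefs[mm]),
                 perm_p = p, stringsAsFactors = FALSE)
    })
    records[[gi]] <- do.call(rbind, rec)
  }
  out <- do.call(rbind, records)
  if (is.null(out))
    out <- data.frame(mir = character(0), gene = character(0),
                      coefficient = numeric(0), perm_p = numeric(0))
  out <- out[out$perm_p < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out$subtype_context <- ""
  if (!is.null(de_context) && nrow(out) > 0) {
    out$subtype_context <- vapply(out$gene, function(g) {
      paste(names(de_context)[vapply(de_context, function(set) g %in% set,
                                     logical(1))], collapse = ",")
    }, character(1))
  }
  stage_log("interactions", "%d significant interactions (p < %g) among %d candidate pairs",
            nrow(out), p_threshold, nrow(pairs))
  class(out) <- c("interaction_table", class(out))
  out
}
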