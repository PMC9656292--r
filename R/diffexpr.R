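#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort the m p-values increasingly, multiply the i-th
#' by m/i, enforce monotonicity from the largest down (running minimum), cap
#' at 1, and restore the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

# Fold change between two groups of log2 values: anti-logged difference of
# group means (geometric-mean ratio), reported as a ratio >= 1 plus the sign
# of the direction (+1: group A above group B).
fold_change_log2 <- function(mean_a, mean_b) {
  diff <- mean_a - mean_b
  list(fc = 2^abs(diff), direction = sign(diff))
}

# SNK p-value matrix for one feature. Means are ranked; each pair is tested
# with the studentized range at the span r of the pair in the ranked order,
# q = |diff| / sqrt(MSE/2 * (1/ni + 1/nj)) (Tukey-Kramer SE adaptation for
# unbalanced groups). Non-significance propagates inward: a pair's p is the
# max raw p over all ranked ranges enclosing it, so no pair can be declared
# significant inside a non-significant range.
snk_pairwise <- function(means, ns, mse, df_err) {
  k <- length(means)
  ord <- order(means)
  p_raw <- matrix(NA_real_, k, k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      i <- ord[a]; j <- ord[b]
      r <- b - a + 1
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- abs(means[i] - means[j]) / se
      p_raw[a, b] <- stats::ptukey(q, nmeans = r, df = df_err,
                                   lower.tail = FALSE)
    }
  }
  p_adj <- matrix(NA_real_, k, k, dimnames = list(names(means), names(means)))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      enclosing <- p_raw[seq_len(a), b:k, drop = FALSE]
      p <- max(enclosing, na.rm = TRUE)
      i <- ord[a]; j <- ord[b]
      p_adj[i, j] <- p_adj[j, i] <- p
    }
  }
  p_adj
}

#' One-way ANOVA with SNK post hoc comparisons
#'
#' Per feature: a one-way ANOVA F test across the subtype groups, followed
#' by Student-Newman-Keuls stepwise comparisons of the ranked group means
#' using the studentized-range distribution (unbalanced group sizes handled
#' with the Tukey-Kramer standard error), plus the pairwise fold change
#' computed on anti-logged group means (data are log2 scale).  Global
#' p-values are BH-adjusted across features.
#'
#' @param m an [expression_matrix()] (log2 scale, complete).
#' @param groups a `subtype_assignment` or a named label vector covering the
#'   samples of `m` to be used (samples absent from `groups` are ignored).
#' @return A data.frame with one row per feature x group pair: columns
#'   `feature`, `global_p`, `bh_q`, `group_a`, `group_b`, `snk_p`,
#'   `fold_change` (>= 1), `direction` (+1 when `group_a` is higher).
#' @export
anova_snk <- function(m, groups) {
  labels <- if (inherits(groups, "subtype_assignment")) groups$labels else groups
  labels <- labels[names(labels) %in% sample_ids(m)]
  if (length(unique(labels)) < 2) stopf("need at least 2 groups")
  if (any(table(labels) < 2)) stopf("every group needs at least 2 samples")
  v <- m$values[, names(labels), drop = FALSE]
  glev <- sort(unique(labels))
  k <- length(glev)
  idx <- lapply(glev, function(g) which(labels == g))
  ns <- vapply(idx, length, integer(1))
  n <- sum(ns)
  df_err <- n - k

  group_var <- vapply(idx, function(ii)
    mean(apply(v[, ii, drop = FALSE], 1, stats::var)), numeric(1))
  if (any(group_var == 0))
    stopf("group '%s' has zero variance across all features",
          glev[which(group_var == 0)[1]])

  pairs <- utils::combn(k, 2)
  res <- vector("list", nrow(v))
  for (f in seq_len(nrow(v))) {
    y <- v[f, ]
    means <- vapply(idx, function(ii) mean(y[ii]), numeric(1))
    names(means) <- glev
    sse <- sum(vapply(seq_len(k), function(g)
      sum((y[idx[[g]]] - means[g])^2), numeric(1)))
    ssb <- sum(ns * (means - mean(y))^2)
    mse <- sse / df_err
    f_stat <- (ssb / (k - 1)) / mse
    global_p <- if (mse == 0) {
      if (ssb == 0) 1 else 0
    } else stats::pf(f_stat, k - 1, df_err, lower.tail = FALSE)
    snk <- if (mse == 0) matrix(1, k, k) else snk_pairwise(means, ns, mse, df_err)
    rows <- lapply(seq_len(ncol(pairs)), function(pp) {
      a <- pairs[1, pp]; b <- pairs[2, pp]
      fc <- fold_change_log2(means[a], means[b])
      data.frame(feature = feature_ids(m)[f], global_p = global_p,
                 group_a = glev[a], group_b = glev[b],
                 snk_p = snk[a, b], fold_change = fc$fc,
                 direction = fc$direction, stringsAsFactors = FALSE)
    })
    res[[f]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  per_feature_p <- tapply(out$global_p, out$feature, `[`, 1)
  q <- bh_adjust(as.numeric(per_feature_p))
  names(q) <- names(per_feature_p)
  out$bh_q <- q[out$feature]
  out[, c("feature", "global_p", "bh_q", "group_a", "group_b",
          "snk_p", "fold_change", "direction")]
}

#' Select differentially expressed features between subtypes
#'
#' A feature is selected when its (BH-adjusted, by default) global p falls
#' below `p_threshold` AND at least one pairwise comparison shows a fold
#' change strictly above `fc_threshold`.
#'
#' @param records output of [anova_snk()] or [two_group_de()].
#' @param p_threshold global significance threshold (default 0.05).
#' @param fc_threshold minimum pairwise fold change (default 1.5, strict).
#' @param use_adjusted apply the threshold to `bh_q` (default) or `global_p`.
#' @return Character vector of selected feature ids.
#' @export
select_subtype_de <- function(records, p_threshold = 0.05, fc_threshold = 1.5,
                              use_adjusted = TRUE) {
  pcol <- if (use_adjusted) records$bh_q else records$global_p
  hit <- pcol < p_threshold & records$fold_change > fc_threshold
  sort(unique(records$feature[hit]))
}

#' Two-group differential expression (unpaired t-test)
#'
#' Per-feature equal-variance unpaired t-test between two sample sets, with
#' BH adjustment across features and the same fold-change summary as
#' [anova_snk()].  Used for tumor-vs-normal and stroma-vs-epithelium
#' contrasts.
#'
#' @param m an [expression_matrix()] (log2 scale, complete).
#' @param samples_a,samples_b disjoint character vectors of sample ids, each
#'   of length >= 2.
#' @return A data.frame: `feature`, `global_p`, `bh_q`, `fold_change`,
#'   `direction` (+1 when group A is higher).
#' @export
two_group_de <- function(m, samples_a, samples_b) {
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stopf("both groups need at least 2 samples")
  if (length(intersect(samples_a, samples_b)) > 0)
    stopf("groups overlap")
  va <- m$values[, samples_a, drop = FALSE]
  vb <- m$values[, samples_b, drop = FALSE]
  na <- ncol(va); nb <- ncol(vb)
  ma <- rowMeans(va); mb <- rowMeans(vb)
  sa <- apply(va, 1, stats::var); sb <- apply(vb, 1, stats::var)
  sp2 <- ((na - 1) * sa + (nb - 1) * sb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t_stat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(t_stat), df = na + nb - 2, lower.tail = FALSE)
  p[se == 0 & ma == mb] <- 1
  p[se == 0 & ma != mb] <- 0
  fc <- fold_change_log2(ma, mb)
  data.frame(feature = feature_ids(m), global_p = p, bh_q = bh_adjust(p),
             fold_change = fc$fc, direction = fc$direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Protected SNK significance call
#'
#' Declares a pairwise difference significant only when the feature's global
#' ANOVA is itself significant at `alpha` (the "protected" protocol) and the
#' stepwise SNK p for the pair falls below `alpha`.
#'
#' @param records output of [anova_snk()].
#' @param alpha significance level for both gates.
#' @param use_adjusted gate the global test on `bh_q` (default) or raw p.
#' @return Logical vector along the rows of `records`.
#' @export
snk_significant <- function(records, alpha = 0.05, use_adjusted = TRUE) {
  gate <- if (use_adjusted) records$bh_q else records$global_p
  gate < alpha & records$snk_p < alpha
}
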