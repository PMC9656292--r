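#' Presence filter
#'
#' Keeps features whose platform detection flag is TRUE in at least
#' `fraction` of the samples (boundary inclusive: a feature detected in
#' exactly 90% of samples passes at `fraction = 0.9`).
#'
#' @param m an [expression_matrix()].
#' @param fraction required detection fraction, in (0, 1].
#' @return A list with the filtered `matrix` and a `report` (list with
#'   `n_features_in`, `n_features_out`, `rule`, `threshold`).
#' @export
presence_filter <- function(m, fraction = 0.90) {
  if (nrow(m$values) == 0 || ncol(m$values) == 0) stopf("empty expression matrix")
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  frac_det <- rowMeans(m$detected)
  keep <- frac_det >= fraction - 1e-12   # inclusive boundary, guard FP noise
  report <- list(n_features_in = nrow(m$values),
                 n_features_out = sum(keep),
                 rule = "presence_filter",
                 threshold = fraction)
  stage_log("preprocess", "presence filter: %d of %d features detected in >= %g%% of samples",
            report$n_features_out, report$n_features_in, 100 * fraction)
  list(matrix = em_subset(m, features = which(keep)), report = report)
}

#' Impute undetected cells
#'
#' Replaces each undetected cell by the feature's minimum detected value (a
#' conservative floor) and sets its flag to detected.  Applied between
#' presence filtering and quantile normalization, which requires complete
#' columns.  Features with no detected value at all are an error.
#'
#' @param m an [expression_matrix()].
#' @return An [expression_matrix()] with a complete value matrix.
#' @export
impute_undetected <- function(m) {
  v <- m$values
  if (all(m$detected)) return(m)
  row_min <- apply(v, 1, function(x) suppressWarnings(min(x, na.rm = TRUE)))
  if (any(!is.finite(row_min)))
    stopf("feature(s) with no detected value: %s",
          paste(feature_ids(m)[!is.finite(row_min)], collapse = ", "))
  idx <- which(!m$detected, arr.ind = TRUE)
  v[idx] <- row_min[idx[, 1]]
  expression_matrix(v, NULL, m$scale_tag)
}

#' Quantile normalization
#'
#' Forces every sample column to share the same value multiset: the sorted
#' values of each column are replaced by the cross-sample mean of the order
#' statistics.  Ties within a column receive the mean of the reference
#' values they span.  Requires a complete matrix (impute first).
#'
#' @param m an [expression_matrix()] with no undetected cells.
#' @return An [expression_matrix()].
#' @export
quantile_normalize <- function(m) {
  if (!all(m$detected))
    stopf("quantile_normalize requires a complete matrix; impute first")
  v <- m$values
  if (ncol(v) == 1) return(m)
  sorted <- apply(v, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(v, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # non-integer ranks (ties) interpolate between adjacent order statistics
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out, NULL, m$scale_tag)
}

#' Median centering
#'
#' Subtracts each feature's median across samples, the standard step before
#' correlation-based clustering of log-scale data.  Idempotent.
#'
#' @param m an [expression_matrix()] with no undetected cells.
#' @return An [expression_matrix()] whose rows have median 0.
#' @export
median_center <- function(m) {
  if (!all(m$detected))
    stopf("median_center requires a complete matrix; impute first")
  med <- apply(m$values, 1, stats::median)
  expression_matrix(m$values - med, NULL, m$scale_tag)
}

#' Low-count filter for count data
#'
#' Drops features whose count is below `min_count` in strictly more than
#' `max_low_fraction` of the samples ("more than" is strict: a feature low
#' in exactly 90% of samples is kept at the default 0.90).
#'
#' @param counts an [expression_matrix()] with `scale_tag = "linear_counts"`.
#' @param min_count counts below this are "low".
#' @param max_low_fraction strict upper bound on the tolerated low fraction.
#' @return A list with `matrix` and `report`, as [presence_filter()].
#' @export
count_filter <- function(counts, min_count = 10, max_low_fraction = 0.90) {
  if (counts$scale_tag != "linear_counts")
    stopf("count_filter expects linear_counts data")
  v <- counts$values
  if (any(v < 0, na.rm = TRUE)) stopf("negative counts")
  low_frac <- rowMeans(v < min_count, na.rm = TRUE)
  keep <- low_frac <= max_low_fraction + 1e-12
  report <- list(n_features_in = nrow(v), n_features_out = sum(keep),
                 rule = "count_filter",
                 threshold = c(min_count = min_count,
                               max_low_fraction = max_low_fraction))
  stage_log("preprocess", "count filter: %d of %d features kept (<%g counts in >%g%% dropped)",
            report$n_features_out, report$n_features_in,
            min_count, 100 * max_low_fraction)
  list(matrix = em_subset(counts, features = which(keep)), report = report)
}

#' PCA-based outlier screen
#'
#' Operationalizes the visual 3D-PCA outlier check: samples are projected on
#' the first `n_components` principal components and flagged when their
#' Euclidean distance from the score centroid exceeds
#' `mean + sd_multiplier * sd` of all such distances.
#'
#' @param m an [expression_matrix()] with no undetected cells.
#' @param n_components number of leading components (default 3).
#' @param sd_multiplier the `k` of the mean + k*sd rule (default 3).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
pca_outlier_screen <- function(m, n_components = 3, sd_multiplier = 3) {
  x <- t(m$values)
  if (nrow(x) < n_components + 1)
    stopf("need at least n_components + 1 samples")
  keep <- apply(x, 2, stats::sd) > 0
  if (!any(keep)) return(character(0))   # degenerate: nothing varies
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  d <- sqrt(rowSums(scale(scores, center = TRUE, scale = FALSE)^2))
  cut <- mean(d) + sd_multiplier * stats::sd(d)
  flagged <- sample_ids(m)[d > cut]
  stage_log("preprocess", "PCA outlier screen: %d of %d samples flagged (k=%g)",
            length(flagged), ncol(m$values), sd_multiplier)
  flagged
}
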