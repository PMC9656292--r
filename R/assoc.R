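#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic sum((O - E)^2 / E) on a contingency table, no
#' continuity correction, df = (r - 1)(c - 1), upper-tail p from the
#' chi-squared distribution.  A zero row or column margin leaves expected
#' counts undefined and is an error.
#'
#' @param tab matrix (or table) of nonnegative counts, at least 2x2.
#' @return A list: `statistic`, `df`, `p`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  check_counts(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stopf("zero row/column margin: expected counts undefined")
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

check_counts <- function(tab) {
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stopf("counts must be nonnegative integers")
  if (sum(tab) == 0) stopf("empty table")
  invisible(tab)
}

#' Fisher's exact test
#'
#' Two-sided exact test on an r x c contingency table with fixed margins,
#' summing the hypergeometric probabilities of all tables no more probable
#' than the observed one (the standard convention).  Uses the network
#' algorithm; tables beyond roughly 10x10 or n = 200 are refused -- use
#' [chi_square()] there.
#'
#' @param tab count matrix, at least 2x2.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  check_counts(tab)
  if (nrow(tab) > 10 || ncol(tab) > 10 || sum(tab) > 200)
    stopf("table too large for exact enumeration; use chi_square()")
  stats::fisher.test(tab)$p.value
}

#' Kruskal-Wallis rank test
#'
#' Rank-based k-group location test with the usual tie correction;
#' H is referred to a chi-squared distribution with k - 1 df.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.
#' @return A list: `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) stopf("values/groups length mismatch")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs at least 2 values")
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * (mean(x) - (n + 1) / 2)^2))
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) return(list(statistic = 0, df = nlevels(groups) - 1, p = 1))
  h <- h / correction
  df <- nlevels(groups) - 1
  list(statistic = h, df = df, p = stats::pchisq(h, df, lower.tail = FALSE))
}

#' Mantel-Haenszel linear-by-linear trend test
#'
#' For a table whose rows (and columns) carry ordinal scores, the statistic
#' is (n - 1) r^2 where r is the count-weighted Pearson correlation of the
#' row and column scores; referred to chi-squared with 1 df.  Unlike the
#' plain chi-square, this test is sensitive to the ordering of the
#' categories.
#'
#' @param tab count matrix with ordered rows, at least 2 rows.
#' @param row_scores,col_scores ordinal scores (defaults 1..r, 1..c).
#' @return A list: `statistic`, `df` (= 1), `p`.
#' @export
mantel_haenszel_trend <- function(tab, row_scores = NULL, col_scores = NULL) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2) stopf("need at least 2 ordered rows")
  check_counts(tab)
  rs <- row_scores %||% seq_len(nrow(tab))
  cs <- col_scores %||% seq_len(ncol(tab))
  n <- sum(tab)
  x <- rep(rs, times = ncol(tab))
  y <- rep(cs, each = nrow(tab))
  w <- as.vector(tab)
  mx <- sum(w * x) / n; my <- sum(w * y) / n
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  if (sxx == 0 || syy == 0)
    return(list(statistic = 0, df = 1L, p = 1))
  r <- sxy / sqrt(sxx * syy)
  stat <- (n - 1) * r^2
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Subtype association report
#'
#' Cross-tabulates the miRNA subtype assignment against each annotation
#' column and applies the appropriate test: chi-square for categorical
#' columns, Kruskal-Wallis for numeric ones.  This reproduces the structure
#' of a subtype-association table (subtype vs molecular labels, MSI, BRAF,
#' stroma content, ...).
#'
#' @param assignment a `subtype_assignment` (or named label vector).
#' @param annotation data.frame with a `sample_id` column.
#' @param columns annotation columns to test (default: all but sample_id).
#' @return A data.frame: `variable`, `test`, `statistic`, `df`, `p`.
#' @export
association_report <- function(assignment, annotation, columns = NULL) {
  labels <- if (inherits(assignment, "subtype_assignment"))
    assignment$labels else assignment
  ann <- annotation[match(names(labels), annotation$sample_id), , drop = FALSE]
  columns <- columns %||% setdiff(names(annotation), "sample_id")
  rows <- lapply(columns, function(col) {
    v <- ann[[col]]
    ok <- !is.na(v)
    if (sum(ok) < 4 || length(unique(v[ok])) < 2) return(NULL)
    if (is.numeric(v)) {
      kw <- kruskal_wallis(v[ok], labels[ok])
      data.frame(variable = col, test = "kruskal_wallis",
                 statistic = kw$statistic, df = kw$df, p = kw$p)
    } else {
      tab <- table(factor(v[ok]), labels[ok])
      if (nrow(tab) < 2 || ncol(tab) < 2) return(NULL)
      cs <- chi_square(tab)
      data.frame(variable = col, test = "chi_square",
                 statistic = cs$statistic, df = cs$df, p = cs$p)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variable = character(0), test = character(0),
                      statistic = numeric(0), df = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  out
}
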