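#' Pearson correlation distance between sample profiles
#'
#' d(i, j) = 1 - r(i, j), with r the Pearson correlation of the two sample
#' columns over features.  With `centered = TRUE` (the discovery setting)
#' profiles are mean-centered, i.e. the usual Pearson correlation; with
#' `centered = FALSE` the correlation is taken about zero (cosine
#' similarity), appropriate for data already centered per feature.
#'
#' @param m an [expression_matrix()] with no undetected cells and at least
#'   3 features.
#' @param centered logical, mean-center each profile first.
#' @return A symmetric `dist`-compatible matrix with zero diagonal, values
#'   in \[0, 2\].
#' @export
pearson_distance <- function(m, centered = TRUE) {
  v <- m$values
  if (!all(m$detected)) stopf("pearson_distance requires a complete matrix")
  if (nrow(v) < 3) stopf("need at least 3 features per profile")
  x <- v
  if (centered) x <- sweep(x, 2, colMeans(x))
  ss <- colSums(x^2)
  zero <- ss == 0
  if (any(zero)) {
    if (centered)
      stopf("zero-variance sample profile(s): %s",
            paste(colnames(v)[zero], collapse = ", "))
    stopf("all-zero sample profile(s): %s",
          paste(colnames(v)[zero], collapse = ", "))
  }
  r <- crossprod(x) / tcrossprod(sqrt(ss))
  d <- 1 - r
  d[d < 0] <- 0          # clip FP noise at the r = 1 boundary
  diag(d) <- 0
  d <- (d + t(d)) / 2    # enforce exact symmetry
  d
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of a precomputed dissimilarity.  `"average"`
#' linkage (UPGMA) replicates the discovery configuration; `"ward"` applies
#' Ward's minimum-variance criterion to the dissimilarities via `ward.D2`
#' (the dissimilarities are treated as distances; `hclust` squares them
#' internally), the common contract when Ward is run on a correlation-based
#' dissimilarity.  Dendrogram leaves are re-ordered deterministically with
#' the tighter (lower-merging) subtree on the left.
#'
#' @param d symmetric dissimilarity matrix (as from [pearson_distance()]).
#' @param linkage `"average"` or `"ward"`.
#' @return An object of class `crcmir_dendrogram` wrapping the `hclust` tree
#'   plus provenance (`linkage`).
#' @export
cluster_samples <- function(d, linkage = c("average", "ward")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("'d' must be a square matrix")
  if (nrow(d) < 2) stopf("need at least 2 items to cluster")
  method <- if (linkage == "average") "average" else "ward.D2"
  hc <- stats::hclust(stats::as.dist(d), method = method)
  hc <- deterministic_order(hc)
  structure(list(hclust = hc, linkage = linkage, n = nrow(d)),
            class = "crcmir_dendrogram")
}

# Reorder each merge so the subtree with the lower previous merge height
# (tighter cluster) sits on the left; leaves compare at height 0 with ties
# broken by smallest leaf index. Flat clusters are unaffected.
deterministic_order <- function(hc) {
  n <- length(hc$labels %||% hc$order)
  sub_height <- function(k) if (k < 0) 0 else hc$height[k]
  sub_minleaf <- numeric(nrow(hc$merge))
  minleaf <- function(k) if (k < 0) -k else sub_minleaf[k]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    ha <- sub_height(a); hb <- sub_height(b)
    la <- minleaf(a); lb <- minleaf(b)
    swap <- hb < ha || (hb == ha && lb < la)
    if (swap) hc$merge[i, ] <- c(b, a)
    sub_minleaf[i] <- min(la, lb)
  }
  # recompute the leaf order by traversing the reordered merges
  ord_of <- vector("list", nrow(hc$merge))
  leaves <- function(k) if (k < 0) -k else ord_of[[k]]
  for (i in seq_len(nrow(hc$merge))) {
    ord_of[[i]] <- c(leaves(hc$merge[i, 1]), leaves(hc$merge[i, 2]))
  }
  hc$order <- ord_of[[nrow(hc$merge)]]
  hc
}

#' @export
print.crcmir_dendrogram <- function(x, ...) {
  cat(sprintf("<crcmir_dendrogram> %d leaves, %s linkage\n", x$n, x$linkage))
  invisible(x)
}

#' Cut a dendrogram into k subtypes
#'
#' Removes the k-1 highest merges and labels the resulting flat clusters
#' S1, S2, ... in order of first-occurring sample (so labels are stable
#' under re-runs).  Ties at the cut height follow merge order, as in
#' `stats::cutree`.
#'
#' @param dend a `crcmir_dendrogram`.
#' @param k number of flat clusters, between 1 and the number of leaves.
#' @return A list of class `subtype_assignment`: `labels` (named character
#'   vector sample -> "S<i>"), `k`, and `provenance` (linkage).
#' @export
cut_k <- function(dend, k) {
  stopifnot(inherits(dend, "crcmir_dendrogram"))
  if (k < 1 || k > dend$n) stopf("k must be in [1, %d]", dend$n)
  raw <- stats::cutree(dend$hclust, k = k)
  first <- unique(raw[order(seq_along(raw))])  # cluster ids by first occurrence
  relab <- stats::setNames(paste0("S", seq_along(first)), first)
  labels <- relab[as.character(raw)]
  names(labels) <- names(raw)
  structure(list(labels = labels, k = as.integer(k),
                 provenance = list(linkage = dend$linkage)),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("<subtype_assignment> k=%d: %s\n", x$k,
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Feature ordering for heatmap display
#'
#' Clusters features with the same distance/linkage machinery as the
#' samples (profiles here are feature rows over samples) and returns the
#' dendrogram leaf order plus a flat feature clustering, the analog of the
#' contiguous miRNA clusters read off the published heatmaps.
#'
#' @param m an [expression_matrix()] with no undetected cells.
#' @param centered passed to [pearson_distance()].
#' @param linkage passed to [cluster_samples()].
#' @param k_features optional flat cut of the feature tree.
#' @return A list: `order` (feature ids in leaf order), `dendrogram`, and
#'   (when `k_features` is given) `clusters` (named vector feature -> label).
#' @export
order_features <- function(m, centered = TRUE,
                           linkage = c("average", "ward"), k_features = NULL) {
  linkage <- match.arg(linkage)
  flipped <- expression_matrix(t(m$values), t(m$detected), m$scale_tag)
  d <- pearson_distance(flipped, centered = centered)
  dend <- cluster_samples(d, linkage = linkage)
  out <- list(order = feature_ids(m)[dend$hclust$order], dendrogram = dend)
  if (!is.null(k_features)) {
    cut <- cut_k(dend, k_features)
    out$clusters <- cut$labels
  }
  out
}

#' Serialize a dendrogram as Newick
#'
#' @param dend a `crcmir_dendrogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
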