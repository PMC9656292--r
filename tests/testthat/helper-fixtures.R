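# Shared fixtures and independent oracles for the test-suite.
options(crcmir.quiet = TRUE)

# small expression matrix with explicit dimnames
em_fixture <- function(values, scale_tag = "log2") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, NULL, scale_tag)
}

random_em <- function(nf, ns, seed, scale_tag = "log2") {
  set.seed(seed)
  em_fixture(matrix(rnorm(nf * ns, mean = 8, sd = 2), nf, ns),
             scale_tag = scale_tag)
}

# --- graph oracles ---------------------------------------------------------

# adjacency list from an edge data.frame (undirected)
edges_to_adj <- function(edges) {
  nodes <- sort(unique(c(edges[[1]], edges[[2]])))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[[1]][i]; b <- edges[[2]][i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# plain BFS shortest-path distances from one node (unit edges)
bfs_distances <- function(adj, from) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[from] <- 0
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

# brute-force closeness and radiality from BFS distances
bfs_centralities <- function(edges) {
  adj <- edges_to_adj(edges)
  nodes <- names(adj)
  n <- length(nodes)
  dmat <- t(vapply(nodes, function(v) bfs_distances(adj, v)[nodes],
                   numeric(n)))
  diam <- max(dmat)
  data.frame(node = nodes,
             closeness = (n - 1) / rowSums(dmat),
             radiality = (rowSums(diam + 1 - dmat) - (diam + 1)) / (n - 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

# exhaustive maximal-clique enumeration for graphs of <= 12 nodes
brute_maximal_cliques <- function(edges, min_size = 1) {
  adj <- edges_to_adj(edges)
  nodes <- names(adj)
  n <- length(nodes)
  stopifnot(n <= 12)
  is_clique <- function(set) {
    if (length(set) < 2) return(TRUE)
    prs <- utils::combn(set, 2)
    all(vapply(seq_len(ncol(prs)), function(i)
      prs[2, i] %in% adj[[prs[1, i]]], logical(1)))
  }
  subsets <- unlist(lapply(seq_len(n), function(k)
    utils::combn(nodes, k, simplify = FALSE)), recursive = FALSE)
  cliques <- Filter(is_clique, subsets)
  keys <- vapply(cliques, paste, character(1), collapse = " ")
  maximal <- vapply(cliques, function(cl) {
    ext <- setdiff(nodes, cl)
    !any(vapply(ext, function(v) is_clique(c(cl, v)), logical(1)))
  }, logical(1))
  out <- cliques[maximal & lengths(cliques) >= min_size]
  lapply(out, sort)
}

# random connected bipartite miR-gene edge set
random_bipartite_edges <- function(n_mir, n_gene, n_edge, seed) {
  set.seed(seed)
  repeat {
    e <- unique(data.frame(
      mir = sample(sprintf("m%02d", seq_len(n_mir)), n_edge, replace = TRUE),
      gene = sample(sprintf("g%02d", seq_len(n_gene)), n_edge, replace = TRUE),
      stringsAsFactors = FALSE))
    if (nrow(e) >= 2) return(e)
  }
}

# two-sided Fisher p for a 2x2 table by full hypergeometric enumeration
fisher_2x2_enumeration <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# naive UPGMA: recompute average-linkage merge heights by exhaustive
# pairwise-mean bookkeeping
naive_upgma_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}
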