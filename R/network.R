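#' Build a subtype regulatory network
#'
#' Turns an interaction table into an undirected bipartite miR-gene graph
#' and retains only the largest connected component (ties broken by node
#' count, then by lexicographically smallest member).  When `de_genes` is
#' given, interactions are first restricted to genes differentially
#' expressed in the subtype under study.
#'
#' @param interactions data.frame with `mir` and `gene` columns.
#' @param de_genes optional character vector; keep only these target genes.
#' @param subtype label stored on the network for provenance.
#' @return An object of class `regulatory_network`: `graph` (igraph with
#'   vertex attributes `name`, `kind`), `subtype`.
#' @export
build_network <- function(interactions, de_genes = NULL,
                          subtype = NA_character_) {
  if (nrow(interactions) == 0) stopf("empty interaction list")
  edges <- interactions
  if (!is.null(de_genes)) edges <- edges[edges$gene %in% de_genes, , drop = FALSE]
  if (nrow(edges) == 0) stopf("no interactions left after DE-gene restriction")
  mirs <- unique(edges$mir)
  genes <- unique(edges$gene)
  clash <- intersect(mirs, genes)
  if (length(clash) > 0)
    stopf("id(s) used as both miR and gene: %s", paste(clash, collapse = ", "))
  g <- igraph::graph_from_data_frame(edges[, c("mir", "gene")],
                                     directed = FALSE)
  igraph::V(g)$kind <- ifelse(igraph::V(g)$name %in% mirs, "miR", "gene")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie on size: smallest lexicographic member wins
    first_member <- vapply(best, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    best <- best[order(first_member)][1]
  }
  keep <- igraph::V(g)[comp$membership == best]
  g <- igraph::induced_subgraph(g, keep)
  stage_log("network", "largest component: %d nodes (%d miR, %d gene), %d edges",
            igraph::vcount(g), sum(igraph::V(g)$kind == "miR"),
            sum(igraph::V(g)$kind == "gene"), igraph::ecount(g))
  structure(list(graph = g, subtype = subtype), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network>%s %d nodes, %d edges\n",
              if (is.na(x$subtype)) "" else paste0(" [", x$subtype, "]"),
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Closeness and radiality centralities
#'
#' For a connected graph with unit edge lengths and geodesic distances d:
#' closeness(v) = (n - 1) / sum_w d(v, w); radiality(v) =
#' sum_w (diam + 1 - d(v, w)) / (n - 1), diam the graph diameter.  Both
#' score a node by its proximity to the whole network rather than by its
#' immediate degree.  A singleton graph scores 0 on both.
#'
#' @param network a [regulatory_network()] (connected by construction).
#' @return A data.frame: `node`, `kind`, `degree`, `closeness`, `radiality`,
#'   `rank_closeness`, `rank_radiality` (rank 1 = most central; ties broken
#'   by degree then id, so ranks are a permutation).
#' @export
network_centralities <- function(network) {
  g <- network$graph
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (n == 1) {
    return(data.frame(node = nm, kind = igraph::V(g)$kind, degree = 0,
                      closeness = 0, radiality = 0,
                      rank_closeness = 1L, rank_radiality = 1L,
                      stringsAsFactors = FALSE))
  }
  dmat <- igraph::distances(g)
  if (any(!is.finite(dmat))) stopf("network is not connected")
  diam <- max(dmat)
  tot <- rowSums(dmat)
  clo <- (n - 1) / tot
  rad <- (rowSums(diam + 1 - dmat) - (diam + 1)) / (n - 1)  # exclude self term
  deg <- igraph::degree(g)
  rank_of <- function(score) {
    ord <- order(-score, -deg, nm)
    r <- integer(n); r[ord] <- seq_len(n); r
  }
  data.frame(node = nm, kind = igraph::V(g)$kind, degree = as.integer(deg),
             closeness = unname(clo), radiality = unname(rad),
             rank_closeness = rank_of(clo), rank_radiality = rank_of(rad),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Attach centralities to the graph (for GML export)
#'
#' @param network a [regulatory_network()].
#' @param centralities output of [network_centralities()]; computed when
#'   missing.
#' @return The network with `closeness`/`radiality` vertex attributes set.
#' @export
annotate_centralities <- function(network, centralities = NULL) {
  cent <- centralities %||% network_centralities(network)
  i <- match(igraph::V(network$graph)$name, cent$node)
  igraph::V(network$graph)$closeness <- cent$closeness[i]
  igraph::V(network$graph)$radiality <- cent$radiality[i]
  network
}

# Maximal cliques of an igraph as a list of character vectors.
maximal_cliques_ids <- function(g, min_size = 1) {
  cl <- igraph::max_cliques(g, min = min_size)
  lapply(cl, function(v) sort(igraph::V(g)$name[v]))
}

#' Overlapping community detection by clique agglomeration (EAGLE-style)
#'
#' Enumerate maximal cliques; cliques of size >= `clique_size_threshold`
#' seed the initial communities, and every node outside all such cliques is
#' added as a singleton (subordinate) community.  Communities are then
#' merged agglomeratively: at each step the pair with the highest overlap
#' similarity |A intersect B| / min(|A|, |B|) is merged (ties broken toward
#' the pair whose union is smallest, then lexicographically), until no pair
#' reaches `merge_threshold`.  Communities smaller than
#' `complex_size_threshold` are finally discarded.
#'
#' A bipartite miR-gene graph is triangle-free, so its maximal cliques are
#' single edges and direct clique agglomeration degenerates.  With
#' `mode = "projection"` (the default for regulatory networks) the algorithm
#' therefore runs on the graph augmented with the one-mode projections:
#' two genes sharing a regulator, and two miRs sharing a target, are joined,
#' which restores cliques (each miR with its targets forms one) while every
#' community still maps back to original nodes.  `mode = "bipartite"` runs
#' on the raw graph.
#'
#' @param network a [regulatory_network()] or a bare igraph.
#' @param clique_size_threshold minimal clique size seeding a community
#'   (default 3).
#' @param complex_size_threshold minimal size of a reported community
#'   (default 2).
#' @param merge_threshold stop merging below this overlap fraction
#'   (default 0.5).
#' @param mode `"projection"` or `"bipartite"` (see above).
#' @return A list of class `community_set`: `communities` (list of sorted
#'   node-id vectors), `parameters`.
#' @export
eagle_communities <- function(network, clique_size_threshold = 3,
                              complex_size_threshold = 2,
                              merge_threshold = 0.5,
                              mode = c("projection", "bipartite")) {
  mode <- match.arg(mode)
  g <- if (inherits(network, "regulatory_network")) network$graph else network
  if (igraph::vcount(g) == 0) stopf("empty network")
  if (mode == "projection") {
    g <- add_one_mode_projections(g)
  }
  cliques <- maximal_cliques_ids(g)
  seeds <- cliques[lengths(cliques) >= clique_size_threshold]
  covered <- unique(unlist(seeds))
  subordinate <- setdiff(igraph::V(g)$name, covered)
  comms <- c(seeds, as.list(subordinate))
  comms <- lapply(comms, sort)

  repeat {
    k <- length(comms)
    if (k < 2) break
    best <- NULL; best_sim <- -Inf; best_union <- Inf; best_tag <- ""
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        inter <- length(intersect(comms[[i]], comms[[j]]))
        if (inter == 0) next
        sim <- inter / min(length(comms[[i]]), length(comms[[j]]))
        uni <- length(comms[[i]]) + length(comms[[j]]) - inter
        tag <- paste(sort(c(comms[[i]][1], comms[[j]][1])), collapse = "|")
        better <- sim > best_sim + 1e-12 ||
          (abs(sim - best_sim) <= 1e-12 &&
             (uni < best_union || (uni == best_union && tag < best_tag)))
        if (better) {
          best_sim <- sim; best <- c(i, j); best_union <- uni; best_tag <- tag
        }
      }
    }
    if (is.null(best) || best_sim < merge_threshold) break
    merged <- sort(union(comms[[best[1]]], comms[[best[2]]]))
    comms <- c(comms[-best], list(merged))
    comms <- unique(comms)
    # drop communities fully contained in another
    keep <- vapply(seq_along(comms), function(i)
      !any(vapply(seq_along(comms), function(j)
        i != j && all(comms[[i]] %in% comms[[j]]), logical(1))), logical(1))
    comms <- comms[keep]
  }
  comms <- comms[lengths(comms) >= complex_size_threshold]
  comms <- comms[order(-lengths(comms),
                       vapply(comms, `[`, character(1), 1))]
  structure(list(communities = comms,
                 parameters = list(clique_size_threshold = clique_size_threshold,
                                   complex_size_threshold = complex_size_threshold,
                                   merge_threshold = merge_threshold,
                                   mode = mode)),
            class = "community_set")
}

# Augment a bipartite graph with its two one-mode projections: nodes of the
# same kind that share a neighbor get an edge. Original edges are kept.
add_one_mode_projections <- function(g) {
  nm <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g)
  extra <- list()
  for (v in seq_along(adj)) {
    nb <- adj[[v]]
    if (length(nb) >= 2) {
      ids <- sort(nm[nb])
      prs <- utils::combn(ids, 2)
      extra[[length(extra) + 1]] <- t(prs)
    }
  }
  if (length(extra) == 0) return(g)
  em <- unique(do.call(rbind, extra))
  existing <- igraph::as_edgelist(g)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  new <- em[!(key(em) %in% key(existing)), , drop = FALSE]
  if (nrow(new) > 0)
    g <- igraph::add_edges(g, t(new))
  igraph::simplify(g)
}

#' @export
print.community_set <- function(x, ...) {
  cat(sprintf("<community_set> %d communities (sizes: %s)\n",
              length(x$communities),
              paste(lengths(x$communities), collapse = ", ")))
  invisible(x)
}

#' Select candidate interactions from a subtype network
#'
#' Union of (a) edges whose two endpoints both belong to the top-central
#' node set -- the intersection of the top-`top_central` lists by closeness
#' and by radiality, padded back to `top_central` nodes by closeness rank --
#' and (b) all edges internal to the most relevant community, defined as the
#' community with the highest mean member closeness (ties to the larger
#' community).  Networks smaller than `top_central` use all nodes.
#'
#' @param network a [regulatory_network()].
#' @param centralities output of [network_centralities()].
#' @param communities a `community_set` (or NULL to use part (a) alone).
#' @param top_central number of central nodes (default 20).
#' @return A data.frame of unique edges: `mir`, `gene`, `via` ("central",
#'   "community" or "central+community").
#' @export
select_candidates <- function(network, centralities, communities = NULL,
                              top_central = 20) {
  g <- network$graph
  n <- igraph::vcount(g)
  k <- min(top_central, n)
  top_clo <- centralities$node[order(centralities$rank_closeness)][seq_len(k)]
  top_rad <- centralities$node[order(centralities$rank_radiality)][seq_len(k)]
  core <- intersect(top_clo, top_rad)
  pad <- setdiff(top_clo, core)
  top_set <- c(core, pad[seq_len(min(length(pad), k - length(core)))])

  el <- igraph::as_edgelist(g)
  kind <- stats::setNames(igraph::V(g)$kind, igraph::V(g)$name)
  flip <- kind[el[, 1]] != "miR"
  el[flip, ] <- el[flip, 2:1]
  edges <- data.frame(mir = el[, 1], gene = el[, 2], stringsAsFactors = FALSE)

  in_central <- edges$mir %in% top_set & edges$gene %in% top_set
  in_comm <- rep(FALSE, nrow(edges))
  if (!is.null(communities) && length(communities$communities) > 0) {
    clo <- stats::setNames(centralities$closeness, centralities$node)
    mean_clo <- vapply(communities$communities, function(members)
      mean(clo[intersect(members, names(clo))]), numeric(1))
    mean_clo[is.na(mean_clo)] <- -Inf
    best <- order(-mean_clo, -lengths(communities$communities))[1]
    members <- communities$communities[[best]]
    in_comm <- edges$mir %in% members & edges$gene %in% members
  }
  sel <- edges[in_central | in_comm, , drop = FALSE]
  sel$via <- ifelse(in_central[in_central | in_comm] &
                      in_comm[in_central | in_comm], "central+community",
                    ifelse(in_central[in_central | in_comm], "central",
                           "community"))
  sel <- unique(sel)
  rownames(sel) <- NULL
  stage_log("network", "selected %d candidate edges (%d via centrality, %d via community)",
            nrow(sel), sum(sel$via != "community"), sum(sel$via != "central"))
  sel
}
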