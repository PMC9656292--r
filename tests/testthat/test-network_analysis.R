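test_that("build_network keeps the largest component and stays bipartite", {
  edges <- data.frame(
    mir = c("m1", "m1", "m2", "m3"),
    gene = c("g1", "g2", "g2", "g3"))     # component {m1,m2,g1,g2} + {m3,g3}
  net <- build_network(edges)
  expect_setequal(igraph::V(net$graph)$name, c("m1", "m2", "g1", "g2"))
  expect_true(igraph::bipartite_mapping(net$graph)$res)
  # single edge is its own network
  net1 <- build_network(data.frame(mir = "mX", gene = "gX"))
  expect_equal(igraph::ecount(net1$graph), 1)
  expect_error(build_network(edges[0, ]), "empty")
  # DE restriction drops edges to non-DE genes
  net2 <- build_network(edges, de_genes = c("g1", "g2"))
  expect_false("g3" %in% igraph::V(net2$graph)$name)
})

test_that("retained component matches brute-force component enumeration", {
  for (seed in 1:10) {
    e <- random_bipartite_edges(5, 6, 9, seed)
    net <- build_network(e)
    # oracle: BFS components over the adjacency list
    adj <- edges_to_adj(e)
    seen <- character(0); comps <- list()
    for (v in names(adj)) {
      if (v %in% seen) next
      comp <- names(which(is.finite(bfs_distances(adj, v))))
      comps[[length(comps) + 1]] <- sort(comp)
      seen <- c(seen, comp)
    }
    sizes <- lengths(comps)
    best <- comps[sizes == max(sizes)]
    first <- vapply(best, min, character(1))
    oracle <- best[[order(first)[1]]]
    expect_setequal(igraph::V(net$graph)$name, oracle)
  }
})

test_that("closeness and radiality match hand values and the BFS oracle", {
  # star with 3 leaves: center closeness 1
  star <- build_network(data.frame(mir = "m", gene = c("g1", "g2", "g3")))
  cs <- network_centralities(star)
  expect_equal(cs$closeness[cs$node == "m"], 1.0)
  # path a-b-c (as miR-gene-miR): b -> 1.0, a -> 2/3; radiality b 2.0, a 1.5
  path <- build_network(data.frame(mir = c("a", "c"), gene = c("b", "b")))
  cp <- network_centralities(path)
  expect_equal(cp$closeness[cp$node == "b"], 1.0)
  expect_equal(cp$closeness[cp$node == "a"], 2 / 3)
  expect_equal(cp$radiality[cp$node == "b"], 2.0)
  expect_equal(cp$radiality[cp$node == "a"], 1.5)
  # 30 random connected graphs vs the brute-force BFS oracle
  for (seed in 1:30) {
    e <- random_bipartite_edges(4, 5, 10, 100 + seed)
    net <- build_network(e)
    got <- network_centralities(net)
    keep <- igraph::V(net$graph)$name
    oracle <- bfs_centralities(data.frame(
      a = c(e$mir), b = c(e$gene))[e$mir %in% keep | e$gene %in% keep, ])
    oracle <- oracle[oracle$node %in% keep, ]
    i <- match(got$node, oracle$node)
    expect_equal(got$closeness, oracle$closeness[i], tolerance = 1e-12)
    expect_equal(got$radiality, oracle$radiality[i], tolerance = 1e-12)
    # ranks are permutations
    expect_setequal(got$rank_closeness, seq_len(nrow(got)))
    expect_setequal(got$rank_radiality, seq_len(nrow(got)))
  }
})

test_that("complete graphs score radiality 1 and agree across measures", {
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- letters[1:5]
  igraph::V(g)$kind <- c("miR", "gene", "gene", "gene", "gene")
  net <- structure(list(graph = g, subtype = NA), class = "regulatory_network")
  cs <- network_centralities(net)
  expect_equal(cs$radiality, rep(1, 5))
  expect_equal(cs$closeness, rep(1, 5))
  expect_identical(order(cs$rank_closeness), order(cs$rank_radiality))
})

test_that("EAGLE on small graphs matches clique expectations", {
  # triangle -> one community of all 3 nodes
  tri <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("a", "c")), directed = FALSE)
  cs <- eagle_communities(tri, 3, 2, mode = "bipartite")
  expect_equal(cs$communities, list(c("a", "b", "c")))
  # two triangles sharing one vertex -> two overlapping communities
  bow <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("a", "c"),
          c("c", "d"), c("d", "e"), c("c", "e")), directed = FALSE)
  cs2 <- eagle_communities(bow, 3, 2, mode = "bipartite")
  expect_equal(length(cs2$communities), 2)
  expect_true(all(vapply(cs2$communities, function(x) "c" %in% x, logical(1))))
  expect_setequal(unlist(cs2$communities), c("a", "b", "c", "d", "e"))
})

test_that("every qualifying maximal clique is contained in some community", {
  for (seed in 1:20) {
    set.seed(600 + seed)
    n <- sample(6:10, 1)
    g <- igraph::sample_gnp(n, 0.45)
    igraph::V(g)$name <- letters[seq_len(n)]
    edges <- igraph::as_edgelist(g)
    if (nrow(edges) == 0) next
    cs <- eagle_communities(g, 3, 2, mode = "bipartite")
    cliques <- brute_maximal_cliques(
      data.frame(a = edges[, 1], b = edges[, 2]), min_size = 3)
    for (cl in cliques) {
      contained <- any(vapply(cs$communities, function(comm)
        all(cl %in% comm), logical(1)))
      expect_true(contained)
    }
    # community members are nodes of the graph
    expect_true(all(unlist(cs$communities) %in% igraph::V(g)$name))
  }
})

test_that("projection mode recovers miR-centred modules on bipartite graphs", {
  # miR hub with 3 targets + separate miR pair sharing 2 targets
  edges <- data.frame(
    mir = c("m1", "m1", "m1", "m2", "m2", "m3", "m3", "m1"),
    gene = c("g1", "g2", "g3", "g4", "g5", "g4", "g5", "g4"))
  net <- build_network(edges)
  cs <- eagle_communities(net, 3, 2, mode = "projection")
  expect_gt(length(cs$communities), 0)
  # the m1 module {m1,g1,g2,g3} appears inside one community
  hit <- any(vapply(cs$communities, function(comm)
    all(c("m1", "g1", "g2", "g3") %in% comm), logical(1)))
  expect_true(hit)
  # all members are real nodes (no projection artifacts leak out)
  expect_true(all(unlist(cs$communities) %in% igraph::V(net$graph)$name))
})

test_that("select_candidates unions the central core and the best community", {
  # star: center + one leaf are the top-2 central nodes
  star <- build_network(data.frame(mir = "m", gene = c("g1", "g2", "g3")))
  cs <- network_centralities(star)
  sel <- select_candidates(star, cs, communities = NULL, top_central = 2)
  top2 <- cs$node[order(cs$rank_closeness)][1:2]
  expect_true(all(sel$mir %in% c(top2, "m")))
  expect_gte(nrow(sel), 1)
  # with an empty community set, selection is part (a) alone
  empty_comm <- structure(list(communities = list(), parameters = list()),
                          class = "community_set")
  sel2 <- select_candidates(star, cs, empty_comm, top_central = 2)
  expect_identical(sel[, c("mir", "gene")], sel2[, c("mir", "gene")])
  # network smaller than top_central: all nodes used, every edge selected
  sel3 <- select_candidates(star, cs, NULL, top_central = 50)
  expect_equal(nrow(sel3), 3)
})

test_that("a planted hub miR reaches the candidate selection on synthetic data", {
  hits <- vapply(1:10, function(seed) {
    co <- generate_cohort(cohort_spec(n_mirs = 30, n_genes = 80, n_edges = 20,
                                      max_regulators_per_gene = 2,
                                      rng_seed = 700 + seed))
    mir <- median_center(quantile_normalize(impute_undetected(co$mirna)))
    mrna <- median_center(impute_undetected(co$mrna))
    pairs <- benchmark_pairs(co$truth, rownames(co$mirna$values),
                             rownames(co$mrna$values), rng_seed = 800 + seed)
    inter <- infer_interactions(mir, mrna, pairs, rng_seed = 900 + seed)
    if (nrow(inter) == 0) return(FALSE)
    net <- build_network(inter)
    cent <- network_centralities(net)
    comm <- eagle_communities(net)
    sel <- select_candidates(net, cent, comm, top_central = 20)
    # hub = planted miR with the most true edges
    hub <- names(sort(table(co$truth$true_edges$mir), decreasing = TRUE))[1]
    hub %in% sel$mir
  }, logical(1))
  expect_gte(sum(hits), 8)
})
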