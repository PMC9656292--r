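#' Export a regulatory network
#'
#' Writes a [regulatory_network()] in a Cytoscape-loadable dialect.  SIF
#' lines take the form `mir regulates gene` (one edge per line).  GML output
#' carries a `kind` node attribute (`miR` / `gene`) and, when centralities
#' have been attached via [network_centralities()], `closeness` and
#' `radiality` node attributes.
#'
#' @param network a [regulatory_network()] with at least one edge.
#' @param path output file path.
#' @param dialect `"SIF"` or `"GML"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, dialect = c("SIF", "GML")) {
  dialect <- match.arg(dialect)
  g <- network$graph
  if (igraph::ecount(g) == 0) stopf("refusing to write an empty network")
  if (dialect == "SIF") {
    el <- igraph::as_edgelist(g)
    kind <- igraph::V(g)$kind
    names(kind) <- igraph::V(g)$name
    # orient every line miR -> gene regardless of internal edge order
    flip <- kind[el[, 1]] != "miR"
    el[flip, ] <- el[flip, 2:1]
    writeLines(paste(el[, 1], "regulates", el[, 2]), path)
  } else {
    igraph::write_graph(g, path, format = "gml")
  }
  invisible(path)
}

#' Read a GML network back into a regulatory network
#'
#' @param path a GML file written by [write_network()].
#' @return A [regulatory_network()].
#' @export
read_network_gml <- function(path) {
  g <- igraph::read_graph(path, format = "gml")
  if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$label))
    igraph::V(g)$name <- igraph::V(g)$label
  structure(list(graph = g, subtype = NA_character_),
            class = "regulatory_network")
}
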