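#' Export a correlation network for external visualization
#'
#' Writes the network with its community partition and importance overlay in
#' a Cytoscape-compatible format. GraphML carries node attributes `assay`,
#' `community`, `is_important` and edge attributes `weight` (absolute
#' Spearman rho), `rho` and `sign`; SIF carries the edge list with a
#' companion `<path>.nodes.tsv` node-attribute table. Nodes and edges are
#' written in lexicographic order, so equal inputs give byte-identical files.
#'
#' @param network A `correlation_network` from [build_network()].
#' @param partition A `network_partition` from [detect_communities()]; must
#'   cover all network nodes.
#' @param important Character vector of important feature ids (may be empty).
#' @param path Output file path.
#' @param format `"graphml"` (default) or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, partition, important = character(0),
                          path, format = "graphml") {
  stopifnot(inherits(network, "correlation_network"))
  if (!format %in% c("graphml", "sif")) {
    abort(sprintf("unknown format '%s'; supported formats: graphml, sif",
                  format))
  }
  g <- network_igraph(network, partition, important)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    edges <- network$edges
    lines <- if (nrow(edges) > 0) {
      sprintf("%s\trho\t%s", edges$from, edges$to)
    } else character(0)
    writeLines(lines, path)
    nodes <- tibble::tibble(
      feature_id = igraph::V(g)$name,
      assay = igraph::V(g)$assay,
      community = igraph::V(g)$community,
      is_important = igraph::V(g)$is_important
    )
    readr::write_tsv(nodes, paste0(path, ".nodes.tsv"))
  }
  invisible(path)
}

# Build an igraph object with export attributes; nodes and edges sorted
# lexicographically by feature id.
network_igraph <- function(network, partition = NULL,
                           important = character(0)) {
  nodes <- network$nodes[order(network$nodes$feature_id), , drop = FALSE]
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "network_partition"))
    idx <- match(nodes$feature_id, partition$membership$feature_id)
    if (anyNA(idx)) {
      abort(sprintf("partition does not cover node(s): %s",
                    paste(utils::head(nodes$feature_id[is.na(idx)], 5),
                          collapse = ", ")))
    }
    nodes$community <- partition$membership$community[idx]
  } else {
    nodes$community <- NA_integer_
  }
  nodes$is_important <- nodes$feature_id %in% important

  edges <- network$edges
  if (nrow(edges) > 0) {
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  }
  igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight", "rho", "sign")],
    directed = FALSE,
    vertices = nodes[, c("feature_id", "assay", "community", "is_important")]
  )
}
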