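#' Metabolite co-occurrence graph
#'
#' Builds the undirected graph whose nodes are the model's metabolites
#' (minus an exclusion set) with an edge between two metabolites whenever
#' they co-occur in at least one reaction. Every edge has unit length: one
#' reaction is one unit of network distance.
#'
#' @param model A [gem()].
#' @param excluded Metabolite ids left out of the graph (e.g. currency
#'   metabolites, whose ubiquity would shrink all distances).
#' @return An [igraph::igraph] with vertex names set to metabolite ids;
#'   isolated metabolites are kept as nodes.
#' @export
metabolite_graph <- function(model, excluded = character()) {
  keep <- setdiff(model$metabolites$id, excluded)
  edges <- character()
  for (r in model$reactions) {
    mets <- intersect(names(r$metabolites), keep)
    if (length(mets) >= 2) {
      pairs <- utils::combn(sort(mets), 2)
      edges <- c(edges, as.character(pairs))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(keep), name = keep)
  if (length(edges)) {
    g <- igraph::add_edges(g, edges)
    g <- igraph::simplify(g)
  }
  g
}

#' Shortest network distances between metabolites
#'
#' Unit-weight shortest-path lengths on [metabolite_graph()] restricted to
#' the requested metabolites. Distances are in reactions.
#'
#' @param graph An [igraph::igraph] from [metabolite_graph()].
#' @param ids Metabolite ids (must be graph vertices).
#' @return Square numeric matrix; `Inf` for unreachable pairs.
#' @export
graph_distances <- function(graph, ids) {
  miss <- setdiff(ids, igraph::V(graph)$name)
  if (length(miss)) {
    stop("metabolite(s) not in graph: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- igraph::distances(graph, v = ids, to = ids)
  dimnames(d) <- list(ids, ids)
  d
}
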