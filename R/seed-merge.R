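#' Seed-based PPI subnetwork
#'
#' Extracts the interaction network around a seed protein set, in one of
#' three expansion modes:
#' \describe{
#'   \item{`induced`}{subgraph induced on the seeds found in the graph
#'     (isolated seeds kept);}
#'   \item{`induced_plus_bridges`}{additionally admits non-seed proteins
#'     adjacent to at least two distinct seeds, with all edges among the
#'     admitted nodes — the smallest expansion that connects seed pairs
#'     through shared interactors;}
#'   \item{`first_neighbors`}{seeds plus all their neighbours, induced.}
#' }
#' The modes are nested: induced ⊆ induced_plus_bridges ⊆ first_neighbors.
#'
#' @param ppi A [ppi_graph()].
#' @param seeds Non-empty character vector of seed identifiers.
#' @param mode Expansion mode (default `induced_plus_bridges`).
#' @return A [ppi_graph()] with attribute `n_seeds_found`.
#' @export
seed_network <- function(ppi, seeds,
                         mode = c("induced_plus_bridges", "induced",
                                  "first_neighbors")) {
  mode <- match.arg(mode)
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("seeds must be non-empty")
  found <- intersect(seeds, ppi$nodes)
  if (!length(found)) {
    stop(sprintf("none of the %d seeds found in the PPI graph (%d missing)",
                 length(seeds), length(seeds)))
  }
  admitted <- switch(mode,
    induced = found,
    induced_plus_bridges = {
      adj <- adjacency_list(ppi)
      nonseed <- setdiff(ppi$nodes, seeds)
      bridge <- nonseed[vapply(adj[nonseed], function(nb) {
        sum(nb %in% found) >= 2L
      }, NA)]
      c(found, bridge)
    },
    first_neighbors = {
      adj <- adjacency_list(ppi)
      unique(c(found, unlist(adj[found], use.names = FALSE)))
    })
  out <- induced_subgraph(ppi, admitted)
  attr(out, "n_seeds_found") <- length(found)
  out
}

#' Merge two PPI networks into a core network
#'
#' `node_intersection` (the default) keeps the proteins present in both
#' networks and every edge of either network between them — the "core"
#' network shared by the drug-target and disease-target interactomes.
#' `union` is the componentwise union.
#'
#' @param g1,g2 [ppi_graph()] objects over the same identifier namespace.
#' @param mode `"node_intersection"` or `"union"`.
#' @return A [ppi_graph()]. An empty node intersection yields a warning and
#'   an empty graph.
#' @export
merge_networks <- function(g1, g2, mode = c("node_intersection", "union")) {
  mode <- match.arg(mode)
  if (mode == "union") {
    return(ppi_graph(nodes = union(g1$nodes, g2$nodes),
                     edges = unique(rbind(g1$edges, g2$edges))))
  }
  keep <- intersect(g1$nodes, g2$nodes)
  if (!length(keep)) {
    warning("node intersection of the two networks is empty")
    return(ppi_graph())
  }
  e <- unique(rbind(g1$edges, g2$edges))
  e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
  ppi_graph(nodes = keep, edges = e)
}
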