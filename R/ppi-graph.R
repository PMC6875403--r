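#' Undirected simple protein-interaction graph
#'
#' The pipeline's network substrate: an undirected, unweighted simple graph
#' over opaque, case-sensitive protein/gene identifiers. No self-loops, no
#' duplicate edges; edges are stored canonically (lexicographically smaller
#' endpoint first, C-locale ordering) so equal graphs have identical
#' representations.
#'
#' @param nodes Character vector of node identifiers (deduplicated, sorted).
#' @param edges Two-column character matrix (or data frame) of edges; must be
#'   canonical and reference `nodes` only. Usually built via [build_graph()].
#' @return An object of class `ppi_graph` with elements `nodes` (sorted
#'   character vector) and `edges` (m x 2 character matrix).
#' @seealso [build_graph()], [seed_network()], [merge_networks()]
#' @export
ppi_graph <- function(nodes = character(), edges = NULL) {
  nodes <- sort_c(unique(as.character(nodes)))
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) stop("edges must have exactly two columns")
    if (!all(edges %in% nodes)) {
      stop("edge endpoints must all appear in the node set")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    i <- match(edges[, 1L], nodes)
    j <- match(edges[, 2L], nodes)
    if (any(i > j)) stop("edges must be canonically oriented (from < to)")
    edges <- edges[order(i, j), , drop = FALSE]
    if (anyDuplicated(paste(edges[, 1L], edges[, 2L], sep = "\r"))) {
      stop("duplicate edges are not allowed")
    }
  }
  colnames(edges) <- c("from", "to")
  structure(list(nodes = nodes, edges = edges), class = "ppi_graph")
}

#' Build a simple undirected graph from raw interaction pairs
#'
#' Drops self-pairs, collapses duplicates in either orientation, and takes the
#' node set to be the endpoints of the surviving edges (so the result never
#' contains isolated nodes).
#'
#' @param pairs Two-column character matrix or data frame of raw pairs, e.g.
#'   the output of [read_edge_list()]. May contain duplicates and self-pairs.
#' @return A [ppi_graph()].
#' @examples
#' g <- build_graph(rbind(c("A", "B"), c("B", "A"), c("A", "A")))
#' n_nodes(g) # 2
#' n_edges(g) # 1
#' @export
build_graph <- function(pairs) {
  if (is.null(pairs) || NROW(pairs) == 0) return(ppi_graph())
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "character"
  if (ncol(pairs) != 2L) stop("pairs must have exactly two columns")
  x <- pairs[, 1L]
  y <- pairs[, 2L]
  keep <- x != y
  x <- x[keep]
  y <- y[keep]
  if (!length(x)) return(ppi_graph())
  # canonical orientation via C-locale ranks (locale-independent)
  lv <- sort_c(unique(c(x, y)))
  xi <- match(x, lv)
  yi <- match(y, lv)
  from <- ifelse(xi <= yi, x, y)
  to <- ifelse(xi <= yi, y, x)
  key <- paste(from, to, sep = "\r")
  keep <- !duplicated(key)
  from <- from[keep]
  to <- to[keep]
  ord <- order(match(from, lv), match(to, lv))
  edges <- cbind(from = from[ord], to = to[ord])
  ppi_graph(nodes = unique(c(from, to)), edges = edges)
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Graph size accessors
#'
#' @param g A [ppi_graph()].
#' @return Integer count of nodes / edges.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' Adjacency list of a graph
#'
#' @param g A [ppi_graph()].
#' @return Named list mapping each node to the character vector of its
#'   neighbours (possibly empty).
#' @export
adjacency_list <- function(g) {
  adj <- stats::setNames(rep(list(character()), n_nodes(g)), g$nodes)
  if (n_edges(g)) {
    ends <- c(g$edges[, 1L], g$edges[, 2L])
    other <- c(g$edges[, 2L], g$edges[, 1L])
    got <- split(other, factor(ends, levels = g$nodes))
    adj[names(got)] <- got
  }
  adj
}

# integer-indexed view used by the centrality kernels
graph_index <- function(g) {
  n <- n_nodes(g)
  adj <- rep(list(integer()), n)
  if (n_edges(g)) {
    i <- match(g$edges[, 1L], g$nodes)
    j <- match(g$edges[, 2L], g$nodes)
    ends <- c(i, j)
    other <- c(j, i)
    got <- split(other, factor(ends, levels = seq_len(n)))
    adj <- lapply(got, as.integer)
  }
  list(n = n, nodes = g$nodes, adj = unname(adj))
}

#' Induced subgraph on a node subset
#'
#' Keeps the requested nodes (including those left isolated) and every edge
#' with both endpoints in the subset.
#'
#' @param g A [ppi_graph()].
#' @param nodes Character vector of nodes to keep; silently intersected with
#'   the graph's node set.
#' @return A [ppi_graph()].
#' @export
induced_subgraph <- function(g, nodes) {
  keep <- intersect(g$nodes, nodes)
  e <- g$edges
  if (nrow(e)) e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
  ppi_graph(nodes = keep, edges = e)
}

#' Test two graphs for equality of node and edge sets
#' @param g1,g2 [ppi_graph()] objects.
#' @return Logical scalar.
#' @export
graphs_equal <- function(g1, g2) {
  identical(g1$nodes, g2$nodes) && identical(unname(g1$edges), unname(g2$edges))
}

# C-locale lexicographic sort: stable across environments
sort_c <- function(x) {
  if (!length(x)) return(as.character(x))
  x[order(x, method = "radix")]
}
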