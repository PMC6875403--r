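#' Node centralities for hub-target screening
#'
#' Six topological scores per node, following the conventions of the
#' CytoNCA family of tools as used in network-pharmacology hub screening:
#'
#' * **DC** — degree centrality, the neighbour count.
#' * **BC** — betweenness centrality, unnormalized: for each unordered pair
#'   of other nodes, the fraction of shortest paths through the node,
#'   summed; unreachable pairs contribute 0.
#' * **CC** — closeness centrality, component-relative: within the node's
#'   connected component of size m, `(m - 1) / sum of distances`; isolated
#'   nodes score 0. Always in \[0, 1\].
#' * **EC** — eigenvector centrality: the nonnegative principal eigenvector
#'   of the adjacency matrix, Euclidean norm 1, over the full (possibly
#'   disconnected) graph.
#' * **NC** — network centrality: the sum over incident edges of the edge
#'   clustering coefficient `z(u,v) / min(dc(u) - 1, dc(v) - 1)` where z is
#'   the number of common neighbours; a zero denominator contributes 0.
#' * **LAC** — local average connectivity: the mean degree of the node's
#'   neighbours within the subgraph they induce, i.e. `2 T(v) / dc(v)` with
#'   T(v) the number of triangles through v; degree-0 nodes score 0.
#'
#' @param g A [ppi_graph()].
#' @return Named numeric vector over `g$nodes`.
#' @name centralities
NULL

#' @rdname centralities
#' @export
degree_centrality <- function(g) {
  lengths(adjacency_list(g))
}

#' @rdname centralities
#' @export
betweenness_centrality <- function(g) {
  # Brandes (2001) accumulation over BFS DAGs; halved because the undirected
  # sweep visits each unordered pair from both endpoints
  idx <- graph_index(g)
  n <- idx$n
  adj <- idx$adj
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1L] <- s
    head <- 1L
    tail <- 1L
    visited <- integer(0)
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      visited <- c(visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(visited)) {
      for (p in preds[[v]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  stats::setNames(bc / 2, idx$nodes)
}

bfs_distances <- function(adj, n, s) {
  dist <- rep(-1L, n)
  dist[s] <- 0L
  queue <- integer(n)
  queue[1L] <- s
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    v <- queue[head]
    head <- head + 1L
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  dist
}

#' @rdname centralities
#' @export
closeness_centrality <- function(g) {
  idx <- graph_index(g)
  n <- idx$n
  cc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- bfs_distances(idx$adj, n, s)
    reach <- dist >= 0L
    m <- sum(reach)
    cc[s] <- if (m > 1L) (m - 1) / sum(dist[reach]) else 0
  }
  stats::setNames(cc, idx$nodes)
}

#' @rdname centralities
#' @param tol Convergence tolerance on the max absolute difference between
#'   successive normalized iterates (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 1000L) {
  idx <- graph_index(g)
  n <- idx$n
  if (!n) return(stats::setNames(numeric(0), character(0)))
  if (!n_edges(g)) {
    warning("graph has no edges; eigenvector centrality is all zero")
    return(stats::setNames(numeric(n), idx$nodes))
  }
  adj <- idx$adj
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    # power step on A + I: same principal eigenvector as A, but convergent
    # on bipartite components where plain iteration oscillates
    y <- x + vapply(adj, function(nb) sum(x[nb]), numeric(1L))
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) <= tol) {
      x <- y
      break
    }
    x <- y
  }
  stats::setNames(x, idx$nodes)
}

#' @rdname centralities
#' @export
network_centrality <- function(g) {
  idx <- graph_index(g)
  adj <- idx$adj
  deg <- lengths(adj)
  nc <- numeric(idx$n)
  if (n_edges(g)) {
    ei <- match(g$edges[, 1L], idx$nodes)
    ej <- match(g$edges[, 2L], idx$nodes)
    for (k in seq_along(ei)) {
      u <- ei[k]
      v <- ej[k]
      denom <- min(deg[u], deg[v]) - 1L
      if (denom > 0L) {
        z <- length(intersect(adj[[u]], adj[[v]]))
        ecc <- z / denom
        nc[u] <- nc[u] + ecc
        nc[v] <- nc[v] + ecc
      }
    }
  }
  stats::setNames(nc, idx$nodes)
}

#' @rdname centralities
#' @export
local_average_connectivity <- function(g) {
  idx <- graph_index(g)
  adj <- idx$adj
  lac <- vapply(seq_len(idx$n), function(v) {
    nb <- adj[[v]]
    if (!length(nb)) return(0)
    sum(vapply(nb, function(u) sum(adj[[u]] %in% nb), numeric(1L))) / length(nb)
  }, numeric(1L))
  stats::setNames(lac, idx$nodes)
}

#' Full centrality table
#'
#' @param g A [ppi_graph()].
#' @return Data frame with one row per node and columns `node`, `dc`, `bc`,
#'   `cc`, `ec`, `nc`, `lac`, sorted by node id.
#' @export
centrality_table <- function(g) {
  if (!n_nodes(g)) {
    return(data.frame(node = character(), dc = integer(), bc = numeric(),
                      cc = numeric(), ec = numeric(), nc = numeric(),
                      lac = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(node = g$nodes,
             dc = as.integer(degree_centrality(g)),
             bc = unname(betweenness_centrality(g)),
             cc = unname(closeness_centrality(g)),
             ec = unname(eigenvector_centrality(g)),
             nc = unname(network_centrality(g)),
             lac = unname(local_average_connectivity(g)),
             stringsAsFactors = FALSE)
}

#' Per-metric median thresholds for hub selection
#'
#' Sample medians of the six centrality columns; for an even node count the
#' median is the midpoint of the two central order statistics (which is how
#' a non-integer degree median can arise).
#'
#' @param table A [centrality_table()] data frame (non-empty).
#' @param strict Hub rule uses strict `>` (default) rather than `>=`.
#' @return A `hub_thresholds` list with `dc_med`, `bc_med`, `cc_med`,
#'   `ec_med`, `nc_med`, `lac_med` and `strict`.
#' @export
median_thresholds <- function(table, strict = TRUE) {
  if (!nrow(table)) stop("cannot take medians of an empty centrality table")
  structure(list(dc_med = stats::median(table$dc),
                 bc_med = stats::median(table$bc),
                 cc_med = stats::median(table$cc),
                 ec_med = stats::median(table$ec),
                 nc_med = stats::median(table$nc),
                 lac_med = stats::median(table$lac),
                 strict = isTRUE(strict)),
            class = "hub_thresholds")
}

#' Select hub nodes by the all-medians rule
#'
#' A node is a hub when every one of its six centralities exceeds the
#' corresponding network-wide median — strictly, under the default rule, so
#' a metric on which all nodes tie disqualifies everyone and the hub set can
#' never exceed half the nodes.
#'
#' @param table A [centrality_table()] data frame.
#' @param thresholds A [median_thresholds()] object.
#' @return Sorted character vector of hub node ids.
#' @export
select_hubs <- function(table, thresholds = median_thresholds(table)) {
  cmp <- if (thresholds$strict) `>` else `>=`
  keep <- cmp(table$dc, thresholds$dc_med) &
    cmp(table$bc, thresholds$bc_med) &
    cmp(table$cc, thresholds$cc_med) &
    cmp(table$ec, thresholds$ec_med) &
    cmp(table$nc, thresholds$nc_med) &
    cmp(table$lac, thresholds$lac_med)
  sort_c(table$node[keep])
}

#' Write a centrality table as TSV (10 significant digits)
#' @param table A [centrality_table()] data frame.
#' @param path Output path.
#' @export
write_centrality_table <- function(table, path) {
  out <- table
  for (col in c("bc", "cc", "ec", "nc", "lac")) {
    out[[col]] <- signif(out[[col]], 10)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
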