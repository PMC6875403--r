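# Brute-force oracles and graph fixtures, kept independent of the package's
# centrality kernels: betweenness by exhaustive simple-path enumeration,
# closeness from igraph's distance matrix, NC/LAC by direct set arithmetic.

rand_pairs <- function(n, p, labels = sprintf("N%02d", seq_len(n))) {
  ut <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  take <- stats::runif(nrow(ut)) < p
  cbind(labels[ut[take, 1L]], labels[ut[take, 2L]])
}

rand_graph <- function(n, p) build_graph(rand_pairs(n, p))

is_connected_graph <- function(g) {
  if (n_nodes(g) <= 1L) return(TRUE)
  adj <- adjacency_list(g)
  seen <- g$nodes[1L]
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == n_nodes(g)
}

rand_connected_graph <- function(n, p) {
  repeat {
    g <- rand_graph(n, p)
    if (n_nodes(g) == n && is_connected_graph(g)) return(g)
  }
}

# named small graphs with hand-checkable structure
named_small_graphs <- function() {
  path_g <- function(n) {
    build_graph(cbind(sprintf("V%d", 1:(n - 1)), sprintf("V%d", 2:n)))
  }
  cycle_g <- function(n) {
    build_graph(rbind(cbind(sprintf("V%d", 1:(n - 1)), sprintf("V%d", 2:n)),
                      c(sprintf("V%d", n), "V1")))
  }
  complete_g <- function(n) {
    build_graph(t(utils::combn(sprintf("V%d", 1:n), 2)))
  }
  star_g <- function(leaves) {
    build_graph(cbind("HUB", sprintf("L%d", seq_len(leaves))))
  }
  k23 <- build_graph(as.matrix(expand.grid(c("A1", "A2"),
                                           c("B1", "B2", "B3"),
                                           stringsAsFactors = FALSE)))
  lollipop <- build_graph(rbind(t(utils::combn(sprintf("K%d", 1:4), 2)),
                                c("K4", "T1"), c("T1", "T2"), c("T2", "T3")))
  list(triangle = complete_g(3), path3 = path_g(3), path5 = path_g(5),
       star4 = star_g(4), cycle6 = cycle_g(6), k5 = complete_g(5),
       k7 = complete_g(7), k23 = k23, lollipop = lollipop)
}

# all graphs the centrality oracle suite runs over
oracle_graph_library <- function(n_random = 50L, seed = 20260921L) {
  withr::with_seed(seed, {
    random <- lapply(seq_len(n_random), function(i) {
      n <- sample(3:7, 1L)
      rand_connected_graph(n, stats::runif(1, 0.3, 0.9))
    })
  })
  c(named_small_graphs(), random)
}

all_shortest_paths_brute <- function(adj, s, t) {
  # enumerate every simple path s -> t, keep the shortest ones
  found <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      found[[length(found) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
  }
  walk(s)
  if (!length(found)) return(list())
  len <- lengths(found)
  found[len == min(len)]
}

oracle_bc <- function(g) {
  adj <- adjacency_list(g)
  nodes <- g$nodes
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  if (length(nodes) < 3L) return(bc)
  for (pair_idx in utils::combn(seq_along(nodes), 2, simplify = FALSE)) {
    s <- nodes[pair_idx[1L]]
    t <- nodes[pair_idx[2L]]
    sp <- all_shortest_paths_brute(adj, s, t)
    if (!length(sp)) next
    inner <- setdiff(nodes, c(s, t))
    for (v in inner) {
      bc[v] <- bc[v] + mean(vapply(sp, function(p) v %in% p, NA))
    }
  }
  bc
}

oracle_cc <- function(g) {
  d <- igraph::distances(as_igraph(g))
  vapply(g$nodes, function(v) {
    dv <- d[v, setdiff(g$nodes, v)]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) 0 else length(dv) / sum(dv)
  }, numeric(1L))
}

oracle_ec <- function(g) {
  A <- matrix(0, n_nodes(g), n_nodes(g), dimnames = list(g$nodes, g$nodes))
  A[g$edges] <- 1
  A <- A + t(A)
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, 1L]
  v <- abs(v) / sqrt(sum(v^2))
  list(vec = stats::setNames(v, g$nodes), lambda = es$values[1L], A = A)
}

oracle_nc <- function(g) {
  adj <- adjacency_list(g)
  deg <- lengths(adj)
  nc <- stats::setNames(numeric(n_nodes(g)), g$nodes)
  for (v in g$nodes) {
    for (u in adj[[v]]) {
      denom <- min(deg[[v]], deg[[u]]) - 1L
      if (denom > 0L) {
        nc[v] <- nc[v] + length(intersect(adj[[v]], adj[[u]])) / denom
      }
    }
  }
  nc
}

oracle_lac <- function(g) {
  adj <- adjacency_list(g)
  vapply(g$nodes, function(v) {
    nb <- adj[[v]]
    if (!length(nb)) return(0)
    sub_deg <- vapply(nb, function(u) length(intersect(adj[[u]], nb)),
                      numeric(1L))
    sum(sub_deg) / length(nb)
  }, numeric(1L))
}

# random centrality table for hub-selection tests
rand_centrality_table <- function(n) {
  data.frame(node = sprintf("N%03d", seq_len(n)),
             dc = sample.int(20L, n, replace = TRUE),
             bc = round(stats::runif(n, 0, 50), 2),
             cc = stats::runif(n),
             ec = stats::runif(n),
             nc = stats::runif(n, 0, 40),
             lac = sample(c(0, round(stats::runif(n, 0, 10), 1)), n,
                          replace = TRUE),
             stringsAsFactors = FALSE)
}
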