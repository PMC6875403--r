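# frozen closed-form values on the named small graphs
test_that("centralities reproduce hand-derived values on named graphs", {
  tri <- build_graph(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  tab <- centrality_table(tri)
  expect_equal(tab$dc, rep(2L, 3))
  expect_equal(tab$bc, rep(0, 3))
  expect_equal(tab$cc, rep(1, 3))
  expect_equal(tab$ec, rep(1 / sqrt(3), 3), tolerance = 1e-9)
  expect_equal(tab$nc, rep(2, 3))
  expect_equal(tab$lac, rep(1, 3))

  path3 <- build_graph(rbind(c("A", "B"), c("B", "C")))
  bc <- betweenness_centrality(path3)
  expect_equal(unname(bc[c("A", "B", "C")]), c(0, 1, 0))
  cc <- closeness_centrality(path3)
  expect_equal(unname(cc[c("A", "B", "C")]), c(2 / 3, 1, 2 / 3))

  star <- build_graph(cbind("HUB", sprintf("L%d", 1:4)))
  expect_equal(betweenness_centrality(star)[["HUB"]], choose(4, 2))
  expect_equal(degree_centrality(star)[["HUB"]], 4L)
  expect_equal(network_centrality(star)[["HUB"]], 0) # no triangles
  expect_equal(local_average_connectivity(star)[["HUB"]], 0)

  # two disjoint triangles: closeness is component-local
  two_tri <- build_graph(rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                               c("X", "Y"), c("Y", "Z"), c("X", "Z")))
  expect_equal(unname(closeness_centrality(two_tri)), rep(1, 6))
})

test_that("handshake and regular-graph symmetries hold on random graphs", {
  withr::local_seed(13)
  for (rep in 1:10) {
    g <- rand_graph(25, stats::runif(1, 0.1, 0.5))
    expect_equal(sum(degree_centrality(g)), 2L * n_edges(g))
  }
  cyc <- named_small_graphs()$cycle6
  ec <- eigenvector_centrality(cyc)
  expect_equal(unname(ec), rep(1 / sqrt(6), 6), tolerance = 1e-8)
})

test_that("all six centralities match brute-force oracles on small graphs", {
  graphs <- oracle_graph_library(n_random = 15L, seed = 90210L)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    lbl <- paste0("graph ", i)
    expect_equal(unname(betweenness_centrality(g)), unname(oracle_bc(g)),
                 tolerance = 1e-9, label = lbl)
    expect_equal(unname(closeness_centrality(g)), unname(oracle_cc(g)),
                 tolerance = 1e-12, label = lbl)
    expect_equal(unname(network_centrality(g)), unname(oracle_nc(g)),
                 tolerance = 1e-12, label = lbl)
    expect_equal(unname(local_average_connectivity(g)),
                 unname(oracle_lac(g)), tolerance = 1e-12, label = lbl)
    eo <- oracle_ec(g)
    expect_equal(unname(eigenvector_centrality(g)), unname(eo$vec),
                 tolerance = 1e-6, label = lbl)
  }
})

test_that("DC/BC/CC/EC agree with igraph on random connected graphs", {
  withr::local_seed(314)
  for (rep in 1:5) {
    g <- rand_connected_graph(15, 0.3)
    ig <- as_igraph(g)
    expect_equal(unname(degree_centrality(g)),
                 unname(igraph::degree(ig)[g$nodes]))
    expect_equal(unname(betweenness_centrality(g)),
                 unname(igraph::betweenness(ig)[g$nodes]),
                 tolerance = 1e-9)
    expect_equal(unname(closeness_centrality(g)),
                 unname(igraph::closeness(ig, normalized = TRUE)[g$nodes]),
                 tolerance = 1e-12)
    ige <- igraph::eigen_centrality(ig)$vector[g$nodes]
    ige <- ige / sqrt(sum(ige^2))
    expect_equal(unname(eigenvector_centrality(g)), unname(ige),
                 tolerance = 1e-6)
  }
})

test_that("eigenvector centrality satisfies the eigen-equation residual", {
  withr::local_seed(27)
  graphs <- c(list(named_small_graphs()$k23, named_small_graphs()$path5),
              lapply(1:5, function(i) rand_graph(20, 0.15)))
  for (g in graphs) {
    if (!n_edges(g)) next
    ec <- eigenvector_centrality(g)
    A <- matrix(0, n_nodes(g), n_nodes(g),
                dimnames = list(g$nodes, g$nodes))
    A[g$edges] <- 1
    A <- A + t(A)
    lambda <- drop(ec %*% A %*% ec)
    expect_lte(max(abs(A %*% ec - lambda * ec)), 1e-8)
    expect_true(all(ec >= -1e-12))
    expect_equal(sum(ec^2), 1, tolerance = 1e-10)
  }
  expect_warning(ec0 <- eigenvector_centrality(ppi_graph(nodes = c("A", "B"))),
                 "no edges")
  expect_equal(unname(ec0), c(0, 0))
})

test_that("closeness is in [0,1], hitting 1 exactly for locally complete nodes", {
  withr::local_seed(55)
  for (rep in 1:10) {
    g <- rand_graph(15, stats::runif(1, 0.1, 0.6))
    cc <- closeness_centrality(g)
    expect_true(all(cc >= 0 & cc <= 1))
    d <- igraph::distances(as_igraph(g))
    for (v in g$nodes) {
      comp <- g$nodes[is.finite(d[v, ])]
      adj_all <- all(d[v, setdiff(comp, v)] == 1)
      expect_equal(unname(cc[v]) == 1, adj_all && length(comp) > 1)
    }
  }
})

test_that("permuting node labels permutes every centrality identically", {
  withr::local_seed(64)
  g <- rand_connected_graph(12, 0.3)
  perm <- stats::setNames(sample(sprintf("Q%02d", 1:12)), g$nodes)
  gp <- build_graph(cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]))
  tab <- centrality_table(g)
  tabp <- centrality_table(gp)
  ord <- match(perm[tab$node], tabp$node)
  for (col in c("dc", "bc", "cc", "ec", "nc", "lac")) {
    expect_equal(tabp[[col]][ord], tab[[col]], tolerance = 1e-8,
                 label = col)
  }
})

test_that("median thresholds use the even-count midpoint rule", {
  tab1 <- rand_centrality_table(1)
  thr1 <- median_thresholds(tab1)
  expect_equal(thr1$dc_med, tab1$dc[1])
  expect_equal(thr1$ec_med, tab1$ec[1])

  tab <- rand_centrality_table(4)
  tab$dc <- c(1L, 2L, 2L, 1L)
  expect_equal(median_thresholds(tab)$dc_med, 1.5)

  withr::local_seed(7)
  tab <- rand_centrality_table(31)
  thr <- median_thresholds(tab)
  for (col in c("dc", "bc", "cc", "ec", "nc", "lac")) {
    v <- sort(tab[[col]])
    expect_equal(thr[[paste0(col, "_med")]], v[16], label = col)
  }
  expect_error(median_thresholds(rand_centrality_table(0)), "empty")
})

test_that("strict hub selection is the six-way conjunction with its size bound", {
  # all nodes identical on one metric -> nobody strictly exceeds the median
  tab <- rand_centrality_table(10)
  tab$cc <- 0.5
  expect_length(select_hubs(tab), 0L)

  # a dominating node over an even-sized table is selected
  tab <- rand_centrality_table(8)
  tab[1, c("dc", "bc", "cc", "ec", "nc", "lac")] <-
    list(100L, 1e3, 1, 1e3, 1e3, 1e3)
  expect_true(tab$node[1] %in% select_hubs(tab))

  withr::local_seed(2024)
  for (rep in 1:20) {
    tab <- rand_centrality_table(sample(5:60, 1))
    thr <- median_thresholds(tab)
    hubs <- select_hubs(tab, thr)
    brute <- tab$node[tab$dc > stats::median(tab$dc) &
                        tab$bc > stats::median(tab$bc) &
                        tab$cc > stats::median(tab$cc) &
                        tab$ec > stats::median(tab$ec) &
                        tab$nc > stats::median(tab$nc) &
                        tab$lac > stats::median(tab$lac)]
    expect_setequal(hubs, brute)
    expect_lte(length(hubs), floor(nrow(tab) / 2))
  }
})
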