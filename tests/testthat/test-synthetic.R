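test_that("generator outputs are pure functions of the spec", {
  spec <- synthetic_spec(seed = 11)
  expect_identical(gen_compound_table(spec), gen_compound_table(spec))
  p1 <- gen_ppi(spec)
  p2 <- gen_ppi(spec)
  expect_true(graphs_equal(p1$graph, p2$graph))
  expect_identical(p1$planted_hubs, p2$planted_hubs)
  expect_identical(gen_compound_target_map(spec),
                   gen_compound_target_map(spec))
  # calling order does not matter: a fresh spec reproduces the same map
  expect_identical(gen_compound_target_map(synthetic_spec(seed = 11)),
                   gen_compound_target_map(spec))
  # different seeds give different planted modules
  expect_false(identical(gen_ppi(synthetic_spec(seed = 12))$planted_hubs,
                         p1$planted_hubs))
})

test_that("compound generator bookkeeping matches the screen module", {
  spec <- synthetic_spec(seed = 42)
  rec <- gen_compound_table(spec)
  gt <- attr(rec, "ground_truth")
  scr <- screen_compounds(rec)
  expect_equal(nrow(scr$candidates), gt$n_candidates)
  expect_equal(scr$n_pass_filter, gt$n_pass)
  expect_equal(scr$n_whitelisted_rescues, gt$n_whitelisted_rescues)
  expect_equal(as.list(per_herb_counts(scr$candidates)), gt$per_herb_counts)
  expect_equal(nrow(shared_compounds(scr$candidates)), gt$n_shared)

  # degenerate pass fractions
  all_pass <- gen_compound_table(synthetic_spec(seed = 1, ob_pass_fraction = 1,
                                                whitelist_fraction = 0))
  expect_equal(nrow(screen_compounds(all_pass)$candidates), nrow(all_pass))
  none <- gen_compound_table(synthetic_spec(seed = 1, ob_pass_fraction = 0,
                                            whitelist_fraction = 0))
  expect_equal(nrow(screen_compounds(none)$candidates), 0L)
})

test_that("planted PPI module has the requested structure", {
  clique <- gen_ppi(synthetic_spec(seed = 3, planted_hub_count = 6,
                                   planted_density = 1,
                                   planted_term_hub_overlap = 5))
  sub <- induced_subgraph(clique$graph, clique$planted_hubs)
  expect_equal(n_edges(sub), choose(6, 2))

  only_module <- gen_ppi(synthetic_spec(seed = 3, ppi_edge_prob = 1e-9,
                                        planted_density = 0.95))
  expect_true(all(only_module$graph$nodes %in% only_module$planted_hubs))

  # mean background degree near the binomial expectation over several seeds
  spec <- synthetic_spec()
  degs <- vapply(1:10, function(s) {
    p <- gen_ppi(synthetic_spec(seed = s))
    bg <- setdiff(p$proteins, p$planted_hubs)
    d <- degree_centrality(p$graph)
    mean(d[intersect(names(d), bg)])
  }, numeric(1))
  n <- spec$ppi_n_background
  expected <- spec$ppi_edge_prob * (n - 1)
  sigma <- sqrt(spec$ppi_edge_prob * (1 - spec$ppi_edge_prob) * (n - 1))
  expect_lt(abs(mean(degs) - expected), 3 * sigma / sqrt(10))
})

test_that("target map covers every planted hub and respects candidates", {
  spec <- synthetic_spec(seed = 9)
  ctmap <- gen_compound_target_map(spec)
  ppi <- gen_ppi(spec)
  expect_true(all(ppi$planted_hubs %in% ctmap$target_id))
  cand <- screen_compounds(gen_compound_table(spec))$candidates
  expect_true(all(ctmap$compound_id %in% cand$compound_id))
  expect_false(any(duplicated(paste(ctmap$compound_id, ctmap$target_id))))
})

test_that("disease set overlaps the drug targets in exactly the planted count", {
  for (s in c(2, 8)) {
    spec <- synthetic_spec(seed = s)
    disease <- gen_disease_targets(spec)
    ctmap <- gen_compound_target_map(spec)
    ov <- disease_overlap(unique(ctmap$target_id), disease)
    expect_equal(length(ov), spec$disease_overlap_count)
    expect_equal(ov, as.character(attr(disease, "overlap")))
    expect_equal(length(disease), spec$n_disease_targets)
  }
  zero <- synthetic_spec(seed = 2, disease_overlap_count = 0)
  dz <- gen_disease_targets(zero)
  expect_length(disease_overlap(unique(gen_compound_target_map(zero)$target_id),
                                dz), 0L)
})

test_that("planted annotation term is the most enriched for the hub query", {
  spec <- synthetic_spec(seed = 31)
  gs <- gen_annotations(spec)
  hubs <- gen_ppi(spec)$planted_hubs
  rows <- enrich(hubs, gs, enrichment_config(universe_mode = "explicit"),
                 universe = attr(gs, "universe"))
  expect_equal(rows$term_id[1], attr(gs, "planted_term"))
  expect_true(rows$significant[1])
})

test_that("gen_all writes a byte-stable bundle whose manifest audits back", {
  spec <- synthetic_spec(seed = 77)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- gen_all(spec, dir1)
  m2 <- gen_all(spec, dir2)
  files <- c("compounds.tsv", "compound_targets.tsv", "disease_targets.txt",
             "ppi.sif", "annotations.gmt", "universe.txt", "manifest.json")
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  # manifest counts match re-reading the written files
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"),
                             simplifyVector = TRUE)
  compounds <- read_compound_table(file.path(dir1, "compounds.tsv"))
  scr <- screen_compounds(compounds)
  expect_equal(nrow(scr$candidates), man$screen$n_candidates)
  g <- read_network(file.path(dir1, "ppi.sif"), "sif")
  expect_equal(n_nodes(g), man$n_ppi_nodes)
  expect_equal(n_edges(g), man$n_ppi_edges)
  ct <- utils::read.delim(file.path(dir1, "compound_targets.tsv"))
  expect_equal(length(unique(ct$target_id)), man$n_drug_targets)
  expect_equal(length(read_gene_list(file.path(dir1, "disease_targets.txt"))),
               man$n_disease_targets)
  expect_true(all(man$planted_hubs %in% g$nodes))
})
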