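test_that("hypergeometric upper tail matches exact combinatorial values", {
  expect_identical(hypergeom_upper_tail(0, 4, 5, 10), 1)
  # P(X >= 3) for K=4, n=5, N=10: (C(4,3)C(6,2) + C(4,4)C(6,1)) / C(10,5)
  expect_equal(hypergeom_upper_tail(3, 4, 5, 10), 66 / 252,
               tolerance = 1e-14)
  expect_error(hypergeom_upper_tail(6, 4, 5, 10), "k must lie")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "must not exceed")
})

test_that("upper tail agrees with one-sided Fisher's exact and is monotone", {
  withr::local_seed(4321)
  for (rep in 1:200) {
    N <- sample(10:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    support <- max(0, n + K - N):min(K, n)
    k <- support[sample.int(length(support), 1)]
    p <- hypergeom_upper_tail(k, K, n, N)
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    pf <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p, pf, tolerance = 1e-10)
    # complementarity with the lower tail
    if (k >= 1) {
      expect_equal(p + stats::phyper(k - 1, K, N - K, n), 1,
                   tolerance = 1e-12)
      expect_lte(p, hypergeom_upper_tail(k - 1, K, n, N) + 1e-15)
    }
  }
})

test_that("enrich recovers a maximal-overlap term and applies BH correctly", {
  gs <- gene_sets(c("T1", "T2", "T3"), rep("d", 3),
                  list(sprintf("A%d", 1:10), sprintf("B%d", 1:10),
                       sprintf("C%d", 1:10)))
  rows <- enrich(sprintf("A%d", 1:10), gs)
  # only the overlapping term is reported, with the minimum possible p
  expect_equal(rows$term_id, "T1")
  expect_equal(rows$k, 10L)
  expect_equal(rows$N, 30L)
  expect_true(rows$significant)

  # planted design: p equals the direct upper-tail call
  withr::local_seed(9)
  universe <- sprintf("G%04d", 1:1000)
  term <- sample(universe, 50)
  query <- c(sample(term, 15), sample(setdiff(universe, term), 5))
  gs2 <- gene_sets(c("T_big", "T_rest"), c("d", "d"),
                   list(term, setdiff(universe, "G0001")))
  rows2 <- enrich(query, gs2, enrichment_config(universe_mode = "explicit"),
                  universe = universe)
  got <- rows2[rows2$term_id == "T_big", ]
  expect_equal(got$p_value, hypergeom_upper_tail(15, 50, 20, 1000))
  # BH: adjusted never below raw, and equals the step-up reconstruction
  expect_true(all(rows2$adj_p >= rows2$p_value - 1e-15))
  expect_equal(rows2$adj_p, stats::p.adjust(rows2$p_value, "BH"))
})

test_that("enrich warns and returns empty on a disjoint query", {
  gs <- gene_sets("T1", "d", list(c("A", "B")))
  expect_warning(rows <- enrich(c("X", "Y"), gs), "does not intersect")
  expect_equal(nrow(rows), 0L)
})

test_that("kappa matches an independent contingency-table computation", {
  skip_if_not_installed("e1071")
  universe <- sprintf("U%03d", 1:100)
  a <- universe[1:30]
  expect_identical(kappa_score(a, a, universe), 1)
  withr::local_seed(12)
  for (rep in 1:50) {
    a <- sample(universe, sample(5:60, 1))
    b <- sample(universe, sample(5:60, 1))
    k1 <- kappa_score(a, b, universe)
    k2 <- kappa_score(b, a, universe)
    expect_equal(k1, k2)
    expect_true(k1 >= -1 && k1 <= 1)
    tab <- table(factor(universe %in% a, c(FALSE, TRUE)),
                 factor(universe %in% b, c(FALSE, TRUE)))
    expect_equal(k1, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
  # degenerate expected-agreement-1 cases
  expect_identical(kappa_score(universe, universe, universe), 1)
  expect_identical(kappa_score(character(), universe, universe), 0)
})

test_that("kappa grouping merges near-duplicate terms and splits disjoint ones", {
  universe <- sprintf("U%03d", 1:120)
  fam1 <- universe[1:30]
  fam2 <- universe[61:90]
  gs <- gene_sets(c("A1", "A2", "B1", "B2"), rep("d", 4),
                  list(fam1, c(fam1[1:28], universe[31:32]),
                       fam2, c(fam2[1:28], universe[91:92])))
  cfg <- enrichment_config(universe_mode = "explicit")
  rows <- enrich(c(fam1[1:10], fam2[1:10]), gs, cfg, universe = universe)
  rows <- group_terms(rows, gs, cfg)
  sig <- rows[rows$significant, ]
  expect_equal(length(unique(sig$group_id)), 2L)
  expect_equal(sum(sig$leading), 2L)
  # the two A-terms share a group; the two B-terms share the other
  expect_equal(sig$group_id[sig$term_id == "A1"],
               sig$group_id[sig$term_id == "A2"])
  expect_equal(sig$group_id[sig$term_id == "B1"],
               sig$group_id[sig$term_id == "B2"])
  expect_false(sig$group_id[sig$term_id == "A1"] ==
                 sig$group_id[sig$term_id == "B1"])

  # identical gene sets: same group, exactly one leading
  gs2 <- gene_sets(c("X", "Y"), c("d", "d"), list(fam1, fam1))
  r2 <- enrich(fam1[1:10], gs2, cfg, universe = universe)
  r2 <- group_terms(r2, gs2, cfg)
  expect_equal(r2$group_id, c(1L, 1L))
  expect_equal(sum(r2$leading), 1L)

  # pairwise-disjoint terms end up in singleton groups (ungated so the
  # grouping structure itself is what is under test)
  cfg_all <- enrichment_config(p_cutoff = 0.999, universe_mode = "explicit")
  gs3 <- gene_sets(c("X", "Y", "Z"), rep("d", 3),
                   list(universe[1:20], universe[41:60], universe[81:100]))
  r3 <- enrich(c(universe[1:5], universe[41:45], universe[81:85]), gs3,
               cfg_all, universe = universe)
  r3 <- group_terms(r3, gs3, cfg_all)
  expect_equal(sort(r3$group_id), 1:3)
})

test_that("raising the kappa threshold only refines the grouping", {
  withr::local_seed(88)
  universe <- sprintf("U%03d", 1:150)
  gs <- gene_sets(sprintf("T%02d", 1:12), rep("d", 12),
                  lapply(1:12, function(i) sample(universe, 35)))
  query <- sample(universe, 40)
  groups_at <- function(kt) {
    cfg <- enrichment_config(p_cutoff = 0.999, kappa_threshold = kt,
                             universe_mode = "explicit")
    rows <- group_terms(enrich(query, gs, cfg, universe), gs, cfg)
    split(rows$term_id, rows$group_id)
  }
  coarse <- groups_at(0.05)
  fine <- groups_at(0.3)
  # every fine group is contained in some coarse group
  for (f in fine) {
    expect_true(any(vapply(coarse, function(cg) all(f %in% cg), NA)))
  }
  expect_gte(length(fine), length(coarse))
})
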