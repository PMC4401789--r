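test_that("internal scores report data density and pattern conformity", {
  # fully observed cluster of identical (varying) rows: pct_na 0, index 1
  m <- pm(c(1, 2, 3, 4,
            1, 2, 3, 4,
            1, 2, 3, 4), 3)
  cs <- cluster_set(structure(c(1L, 1L, 1L), names = rownames(m)))
  sc <- cluster_internal_scores(m, cs, min_overlap = 3)
  expect_equal(sc$pct_na, 0)
  expect_equal(sc$index, 1)

  # half the cells missing -> pct_na 50
  m2 <- pm(c(1, 2, NA, NA,
             NA, NA, 3, 4), 2)
  cs2 <- cluster_set(structure(c(1L, 1L), names = rownames(m2)))
  expect_equal(cluster_internal_scores(m2, cs2, 1)$pct_na, 50)

  # two anti-correlated members -> rhobar -1 -> negative index
  m3 <- pm(c(1, 2, 3, 4,
             4, 3, 2, 1), 2)
  cs3 <- cluster_set(structure(c(1L, 1L), names = rownames(m3)))
  sc3 <- cluster_internal_scores(m3, cs3, 3)
  expect_equal(sc3$index, -1)

  # direct evaluation of the stated formula on a mixed cluster
  m4 <- pm(c(1, 2, 3, 4,
             2, 4, 6, 8,
             4, 3, 2, 1), 3)
  cs4 <- cluster_set(structure(c(1L, 1L, 1L), names = rownames(m4)))
  w <- rowSums(abs(m4))
  rhobar <- c(mean(c(1, -1)), mean(c(1, -1)), mean(c(-1, -1)))
  expect_equal(cluster_internal_scores(m4, cs4, 3)$index,
               sum(w * rhobar) / sum(w), tolerance = 1e-12)

  # singletons report density but no index
  cs5 <- cluster_set(structure(c(1L, 2L, 2L), names = rownames(m4)))
  sc5 <- cluster_internal_scores(m4, cs5, 3)
  expect_true(is.na(sc5$index[sc5$cluster_id == 1]))
  expect_equal(sc5$pct_na[sc5$cluster_id == 1], 0)
  expect_error(cluster_internal_scores(m4,
    cluster_set(structure(1L, names = "nope")), 3), "missing from")
})

test_that("PPI scores count within-cluster edges and weight", {
  g <- merge_ppi(list(data.frame(a = c("A", "A", "C"),
                                 b = c("B", "D", "D"),
                                 weight = c(2, 9, 1))))
  cs <- cluster_set(structure(c(1L, 1L, 1L, 2L),
                              names = c("A", "B", "C", "E")))
  sc <- cluster_ppi_scores(g, cs)
  expect_equal(sc$ppi_edges[sc$cluster_id == 1], 1)     # only A-B inside
  expect_equal(sc$ppi_edge_weight[sc$cluster_id == 1], 2)
  expect_equal(sc$ppi_edges[sc$cluster_id == 2], 0)
  expect_equal(sc$ppi_edge_weight[sc$cluster_id == 2], 0)

  # a clique of four with unit weights has 6 edges, weight 6
  cl <- t(combn(c("W", "X", "Y", "Z"), 2))
  g2 <- merge_ppi(list(data.frame(a = cl[, 1], b = cl[, 2], weight = 1)))
  cs2 <- cluster_set(structure(rep(1L, 4), names = c("W", "X", "Y", "Z")))
  sc2 <- cluster_ppi_scores(g2, cs2)
  expect_equal(sc2$ppi_edges, 6)
  expect_equal(sc2$ppi_edge_weight, 6)
})

test_that("GO screen matches the brute-force hypergeometric tail", {
  # universe of 20, term annotates 5, cluster of 5 holds 4 of them
  universe <- paste0("G", 1:20)
  term_genes <- paste0("G", 1:5)
  annot <- data.frame(gene = term_genes, term = "GO:X")
  cs <- cluster_set(structure(rep(1L, 5),
                              names = c(paste0("G", 1:4), "G10")))
  p_oracle <- oracle_hyper_tail(4, 5, 20, 5)
  expect_equal(p_oracle, 76 / 15504, tolerance = 1e-15)
  sc <- cluster_go_scores(annot, cs, universe, p_cut = 0.01)
  expect_equal(sc$go_terms_enriched, 1L)     # p ~ 0.0049 < 0.01, >= 2 genes
  expect_equal(sc$go_terms_per_gene, 1 / 5)
  expect_equal(sc$go_mean_count_over_expected, 4 / (5 / 20 * 5))

  # single-gene terms are discarded regardless of p
  annot2 <- data.frame(gene = "G1", term = "GO:single")
  sc2 <- cluster_go_scores(annot2, cs, universe, p_cut = 1)
  expect_equal(sc2$go_terms_enriched, 0L)

  # no annotated genes in the cluster -> (0, 0, NA)
  cs3 <- cluster_set(structure(rep(1L, 3), names = paste0("G", 15:17)))
  sc3 <- cluster_go_scores(annot, cs3, universe)
  expect_equal(sc3$go_terms_enriched, 0L)
  expect_true(is.na(sc3$go_mean_count_over_expected))
  expect_error(cluster_go_scores(annot, cs, character(0)), "empty")
})

test_that("GO screen agrees with the oracle across random universes", {
  set.seed(21)
  for (rep in 1:10) {
    n_univ <- sample(15:50, 1)
    universe <- paste0("G", seq_len(n_univ))
    n_ann <- sample(3:10, 1)
    annot <- data.frame(gene = sample(universe, n_ann), term = "GO:T")
    k <- sample(3:8, 1)
    members <- sample(universe, k)
    cs <- cluster_set(structure(rep(1L, k), names = members))
    q <- length(intersect(members, annot$gene))
    if (q < 2) next
    p_or <- oracle_hyper_tail(q, n_ann, n_univ, k)
    # screen with the cut just above/below the oracle p flips term retention
    above <- cluster_go_scores(annot, cs, universe, p_cut = p_or * 1.001)
    below <- cluster_go_scores(annot, cs, universe, p_cut = p_or * 0.999)
    expect_equal(above$go_terms_enriched, 1L)
    expect_equal(below$go_terms_enriched, 0L)
  }
})

test_that("permissive screen returns every term present in >= 1 cluster gene", {
  universe <- paste0("G", 1:12)
  annot <- data.frame(gene = c("G1", "G2", "G2", "G5", "G9"),
                      term = c("T1", "T1", "T2", "T3", "T4"))
  cs <- cluster_set(structure(rep(1L, 4), names = paste0("G", 1:4)))
  sc <- cluster_go_scores(annot, cs, universe, p_cut = 1 + 1e-9,
                          min_genes = 1L)
  expect_equal(sc$go_terms_enriched, 2L)   # T1 (2 genes), T2 (1 gene)
})

test_that("random clusters are seeded, disjoint and size-matched", {
  template <- cluster_set(structure(c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L),
                                    names = paste0("t", 1:10)))
  ents <- paste0("E", 1:20)
  r1 <- random_clusters(ents, template, n_clusters = 2, seed = 9)
  r2 <- random_clusters(ents, template, n_clusters = 2, seed = 9)
  expect_identical(r1, r2)                       # deterministic given seed
  expect_false(anyDuplicated(names(r1)) > 0)     # non-overlapping
  expect_true(all(table(r1) %in% c(3L, 4L)))     # sizes from the template
  expect_true(all(names(r1) %in% ents))
  r3 <- random_clusters(ents, template, n_clusters = 2, seed = 10)
  expect_false(identical(names(r1), names(r3)))
  expect_error(random_clusters(paste0("E", 1:100), template,
                               n_clusters = 70, seed = 1), "available")
})

test_that("Welch comparison matches stats::t.test and handles degeneracy", {
  real <- data.frame(cluster_id = 1:3, n_members = 3, index = c(10, 11, 12))
  rand <- data.frame(cluster_id = 1:3, n_members = 3, index = c(0, 1, 2))
  rep_ <- compare_real_vs_random(real, rand)
  w <- rep_$welch$index
  oracle <- t.test(real$index, rand$index)
  expect_equal(w$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(oracle$parameter), tolerance = 1e-12)
  expect_equal(w$p, oracle$p.value, tolerance = 1e-12)
  expect_lt(w$p, 0.01)

  # identical vectors on both sides -> t = 0, p = 1
  rep2 <- compare_real_vs_random(real, real)
  expect_equal(rep2$welch$index$t, 0)
  expect_equal(rep2$welch$index$p, 1)

  # one usable value on a side -> metric skipped with a warning
  rand3 <- data.frame(cluster_id = 1:3, n_members = 3,
                      index = c(5, NA, NA))
  expect_warning(rep3 <- compare_real_vs_random(real, rand3), "skipped")
  expect_null(rep3$welch$index)
})
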