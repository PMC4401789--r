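edge_df <- function(a, b, w, src = NULL) {
  d <- data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE)
  if (!is.null(src)) d$source <- src
  d
}

toy_cc <- function() {
  # euclidean: {A,B,C} {D,E}; spearman: {A,B} {C,D,E}
  cluster_collection(
    euclidean = cluster_set(structure(c(1L, 1L, 1L, 2L, 2L),
                                      names = c("A", "B", "C", "D", "E")),
                            "euclidean"),
    spearman = cluster_set(structure(c(1L, 1L, 2L, 2L, 2L),
                                     names = c("A", "B", "C", "D", "E")),
                           "spearman"))
}

test_that("PPI sources merge with canonical orientation and summed weight", {
  g <- merge_ppi(list(edge_df("A", "B", 1, "string"),
                      edge_df("B", "A", 2, "genemania")))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 3)
  expect_equal(igraph::E(g)$provenance, "string;genemania")

  # disjoint sets just union; empty input -> empty graph; max-combine option
  g2 <- merge_ppi(list(edge_df(c("A", "C"), c("B", "D"), c(1, 1)),
                       edge_df("E", "F", 2)))
  expect_equal(igraph::ecount(g2), 3L)
  expect_equal(igraph::ecount(merge_ppi(list())), 0L)
  g3 <- merge_ppi(list(edge_df("A", "B", 1), edge_df("B", "A", 2)),
                  combine = "max")
  expect_equal(igraph::E(g3)$weight, 2)
  expect_error(merge_ppi(list(edge_df("A", "B", -1))), "negative")
})

test_that("co-cluster pairs honour inclusive/exclusive modes and multiplicity", {
  cc <- toy_cc()
  inc <- cocluster_pairs(cc, "inclusive")
  exc <- cocluster_pairs(cc, "exclusive")
  key <- function(p) paste(p$a, p$b)
  # A-B co-cluster in both kinds -> multiplicity 2, present in both modes
  expect_true("A B" %in% key(inc) && "A B" %in% key(exc))
  expect_equal(inc$multiplicity[key(inc) == "A B"], 2L)
  # B-C co-cluster in euclidean only -> inclusive yes (mult 1), exclusive no
  expect_true("B C" %in% key(inc))
  expect_equal(inc$multiplicity[key(inc) == "B C"], 1L)
  expect_false("B C" %in% key(exc))
  expect_error(cocluster_pairs(cc, kinds = character(0)), "at least one")
  expect_error(cocluster_pairs(cc, kinds = "sed"), "unknown")
})

test_that("CFN is exactly PPI edges among co-clustered pairs", {
  cc <- cluster_collection(
    euclidean = cluster_set(structure(c(1L, 1L, 1L, 2L, 2L),
                                      names = c("A", "B", "C", "D", "E")),
                            "euclidean"))
  ppi <- merge_ppi(list(edge_df(c("A", "A", "D"), c("B", "D", "E"),
                                c(1, 5, 2))))
  cfn <- build_cfn(ppi, cocluster_pairs(cc, "inclusive"))
  el <- igraph::as_edgelist(cfn)
  expect_equal(nrow(el), 2L)
  expect_setequal(paste(el[, 1], el[, 2]), c("A B", "D E"))
  # isolated nodes are dropped
  expect_false("C" %in% igraph::V(cfn)$name)

  # no PPI edge inside any cluster -> empty graph
  ppi2 <- merge_ppi(list(edge_df("A", "D", 1)))
  expect_equal(igraph::ecount(build_cfn(ppi2, cocluster_pairs(cc))), 0L)

  # PPI entirely inside clusters -> CFN = PPI
  ppi3 <- merge_ppi(list(edge_df(c("A", "B"), c("B", "C"), c(1, 1))))
  cfn3 <- build_cfn(ppi3, cocluster_pairs(cc))
  expect_equal(igraph::ecount(cfn3), 2L)
})

test_that("CFN edges are a subset of both PPI and co-cluster pairs", {
  set.seed(5)
  for (rep in 1:5) {
    ents <- paste0("P", 1:12)
    cc <- cluster_collection(
      euclidean = cluster_set(structure(sample(1:3, 12, TRUE),
                                        names = ents), "euclidean"),
      spearman = cluster_set(structure(sample(1:3, 12, TRUE),
                                       names = ents), "spearman"))
    pairs <- t(combn(ents, 2))
    hit <- runif(nrow(pairs)) < 0.3
    ppi <- merge_ppi(list(edge_df(pairs[hit, 1], pairs[hit, 2],
                                  runif(sum(hit)))))
    cop <- cocluster_pairs(cc, "inclusive")
    cfn <- build_cfn(ppi, cop)
    if (igraph::ecount(cfn) == 0) next
    el <- igraph::as_edgelist(cfn)
    cfn_keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    ppi_el <- igraph::as_edgelist(ppi)
    expect_true(all(cfn_keys %in%
                      paste(pmin(ppi_el[, 1], ppi_el[, 2]),
                            pmax(ppi_el[, 1], ppi_el[, 2]))))
    expect_true(all(cfn_keys %in% paste(cop$a, cop$b)))
  }
})

test_that("negative-edge transform follows exp(20 rho) and is monotone", {
  expect_equal(transform_negative_edge(-0.5), exp(-10))
  expect_equal(transform_negative_edge(-0.5), 4.54e-5, tolerance = 1e-3)
  expect_equal(transform_negative_edge(-1), exp(-20))
  expect_equal(transform_negative_edge(-1e-9), 1, tolerance = 1e-6)
  expect_error(transform_negative_edge(0), "rho < 0")
  expect_error(transform_negative_edge(0.2), "rho < 0")
  rho <- sort(runif(20, -1, -1e-3))
  out <- transform_negative_edge(rho)
  expect_true(all(diff(out) > 0))
  expect_true(all(out > 0 & out < 1))
})

test_that("CCCN keeps co-clustered pairs passing the |rho| threshold", {
  # rows engineered so rho(A,B)=1, rho(A,C)=-0.1, rho(A,D)=-1
  m <- pm(c(1, 2, 3, 4, 5,
            2, 4, 6, 8, 10,
            3, 5, 1, 2, 4,
            5, 4, 3, 2, 1,
            1, 3, 2, 5, 4), 5, entities = c("A", "B", "C", "D", "E"))
  pairs <- data.frame(a = c("A", "A", "A"), b = c("B", "C", "D"),
                      multiplicity = c(2L, 1L, 3L))
  g <- build_cccn(m, pairs, rho_threshold = 0.5)
  el <- igraph::as_edgelist(g)
  keys <- paste(el[, 1], el[, 2])
  expect_true("A B" %in% keys)            # rho 1 >= 0.5
  expect_false("A C" %in% keys)           # rho 0.4 < 0.5
  expect_true("A D" %in% keys)            # |-1| >= 0.5, negative edge
  # E correlates with others but is not co-clustered -> never an edge
  expect_false("E" %in% igraph::V(g)$name)

  eAB <- igraph::E(g)[keys == "A B"]
  eAD <- igraph::E(g)[keys == "A D"]
  expect_equal(eAB$sign, "+"); expect_equal(eAD$sign, "-")
  expect_equal(eAB$weight, 1)                       # positive: weight = rho
  expect_equal(eAD$weight, exp(-20), tolerance = 1e-9)
  expect_equal(eAB$thickness, 1 * 2)                # |rho| x multiplicity
  expect_equal(eAD$thickness, 1 * 3)
  # node attributes: totals and class
  expect_equal(igraph::V(g)[["A"]]$node_class, "activating")
  expect_equal(igraph::V(g)[["A"]]$total_phospho, 15)
})

test_that("CCCN at threshold ~0 with all pairs is the full correlation graph", {
  m <- phospho_matrix(random_na_matrix(6, 8, 0, seed = 9), "protein")
  ents <- rownames(m)
  allp <- t(combn(ents, 2))
  pairs <- data.frame(a = allp[, 1], b = allp[, 2], multiplicity = 1L)
  g <- build_cccn(m, pairs, rho_threshold = 1e-9)
  expect_equal(igraph::ecount(g), choose(6, 2))
})

test_that("network statistics match closed forms on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  s <- network_stats(tri)
  expect_equal(s$clustering_coefficient, 1)
  expect_equal(s$diameter, 1)
  expect_equal(s$mean_path_length, 1)

  path3 <- igraph::make_graph(~ a - b, b - c)
  s2 <- network_stats(path3)
  expect_equal(s2$clustering_coefficient, 0)
  expect_equal(s2$diameter, 2)

  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("n", 1:6)
  s3 <- network_stats(k6)
  expect_equal(s3$clustering_coefficient, 1)
  expect_equal(s3$diameter, 1)
  expect_equal(s3$mean_path_length, 1)
  expect_error(network_stats(igraph::make_empty_graph(0)), "empty")
})

test_that("power-law fit on a preferential-attachment graph is sane", {
  set.seed(1)
  g <- igraph::sample_pa(2000, m = 2, directed = FALSE)
  igraph::V(g)$name <- paste0("v", 1:2000)
  s <- network_stats(g, degree_min_for_fit = 10L)
  expect_gte(s$powerlaw_alpha, 1.0)
  expect_lte(s$powerlaw_alpha, 3.5)
  expect_gt(s$powerlaw_r2, 0.5)
  # cross-check against a direct log-log regression of the degree counts
  tab <- table(igraph::degree(g))
  fit <- lm(log(as.numeric(tab)) ~ log(as.numeric(names(tab))))
  expect_equal(s$powerlaw_alpha, -unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(s$powerlaw_r2, summary(fit)$r.squared, tolerance = 1e-10)
})

test_that("fraction subnetwork annotates enrichment and drops unvalued nodes", {
  g <- merge_ppi(list(edge_df(c("A", "B", "C"), c("B", "C", "D"), 1)))
  vals <- c(A = 1, B = 5, C = 0.2)
  sub <- fraction_subnetwork(g, vals)
  expect_setequal(igraph::V(sub)$name, c("A", "B", "C"))  # D dropped
  expect_equal(igraph::V(sub)[["A"]]$color, "green")      # neutral
  expect_equal(igraph::V(sub)[["B"]]$color, "yellow")     # enriched
  expect_equal(igraph::V(sub)[["C"]]$color, "blue")       # de-enriched
  expect_gt(igraph::V(sub)[["B"]]$size, igraph::V(sub)[["C"]]$size)
})

test_that("graph export writes GraphML plus node and edge tables", {
  g <- merge_ppi(list(edge_df(c("A", "B"), c("B", "C"), c(1, 2))))
  prefix <- withr::local_tempfile()
  write_graph_outputs(g, prefix)
  expect_true(file.exists(paste0(prefix, ".graphml")))
  back <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::ecount(back), 2L)
  edges <- read.delim(paste0(prefix, "_edges.tsv"))
  expect_equal(nrow(edges), 2L)
  expect_true("weight" %in% names(edges))
})
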