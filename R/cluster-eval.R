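#' Internal cluster scores: data density and pattern conformity
#'
#' For each cluster the percent of missing cells in its submatrix is
#' reported, together with a quantitative index combining data density and
#' conformity to the shared pattern, weighted by total phosphopeptide
#' signal:
#' `index = (1 - pctNA/100) * sum_i w_i * rhobar_i / sum_i w_i`,
#' where `rhobar_i` is the mean pairwise-complete Spearman correlation of
#' member `i` with the other members and `w_i = sum |signal_i|`.  Singleton
#' clusters have no pairwise pattern, so their index is `NA` (percent NA is
#' still reported).
#'
#' @param m a [phospho_matrix()] covering all cluster members.
#' @param cs a `phospho_clusters` partition (or named integer vector).
#' @param min_overlap minimum shared observations for a defined pairwise rho.
#' @return data.frame: `cluster_id`, `n_members`, `pct_na`, `index`.
#' @export
cluster_internal_scores <- function(m, cs, min_overlap = 3L) {
  if (!all(names(cs) %in% rownames(m)))
    stop("cluster members missing from the matrix: ",
         paste(utils::head(setdiff(names(cs), rownames(m)), 5L), collapse = ", "))
  do.call(rbind, lapply(split(names(cs), cs), function(members) {
    sub <- m[members, , drop = FALSE]
    pct_na <- 100 * mean(is.na(sub))
    if (length(members) < 2L)
      return(data.frame(cluster_id = cs[[members[1L]]],
                        n_members = 1L, pct_na = pct_na, index = NA_real_))
    rho <- suppressWarnings(
      stats::cor(t(sub), method = "spearman", use = "pairwise.complete.obs"))
    ov <- tcrossprod(!is.na(sub) * 1)
    rho[ov < min_overlap] <- NA_real_
    diag(rho) <- NA_real_
    rhobar <- rowMeans(rho, na.rm = TRUE)
    w <- rowSums(abs(sub), na.rm = TRUE)
    ok <- is.finite(rhobar) & w > 0
    index <- if (!any(ok)) NA_real_ else
      (1 - pct_na / 100) * sum(w[ok] * rhobar[ok]) / sum(w[ok])
    data.frame(cluster_id = cs[[members[1L]]], n_members = length(members),
               pct_na = pct_na, index = index)
  }))
}

#' PPI support per cluster
#'
#' Counts interaction edges with both endpoints inside the cluster and sums
#' their weights.
#'
#' @param g merged PPI igraph.
#' @param cs a `phospho_clusters` partition.
#' @return data.frame: `cluster_id`, `n_members`, `ppi_edges`,
#'   `ppi_edge_weight`.
#' @export
cluster_ppi_scores <- function(g, cs) {
  el <- if (igraph::ecount(g)) igraph::as_edgelist(g) else
    matrix(character(0), 0, 2)
  w <- if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0)
  if (is.null(w)) w <- rep(1, nrow(el))
  do.call(rbind, lapply(split(names(cs), cs), function(members) {
    inside <- el[, 1L] %in% members & el[, 2L] %in% members
    data.frame(cluster_id = cs[[members[1L]]], n_members = length(members),
               ppi_edges = sum(inside), ppi_edge_weight = sum(w[inside]))
  }))
}

hypergeom_tail_p <- function(q, m_ann, n_universe, k_cluster) {
  # P[X >= q], X ~ Hypergeometric(universe, annotated, cluster draw)
  stats::phyper(q - 1L, m_ann, n_universe - m_ann, k_cluster,
                lower.tail = FALSE)
}

#' GO-term over-representation per cluster
#'
#' For every term annotating at least one cluster gene, a hypergeometric
#' over-representation p-value (upper tail, at least the observed count) is
#' computed against the gene universe.  Terms are kept if `p < p_cut` and at
#' least `min_genes` (default 2: single-gene terms are discarded) cluster
#' genes carry them.  Reported per cluster: the number of enriched terms,
#' terms per gene, and the mean over enriched terms of observed count over
#' the hypergeometric expectation `(term frequency in universe) * cluster
#' size`.  A cluster with no annotated genes gets `(0, 0, NA)`; a cluster
#' with annotated genes but no enriched term gets mean ratio 0.
#'
#' @param annot data.frame with columns `gene`, `term` (flat annotations; no
#'   ontology propagation is performed).
#' @param cs a `phospho_clusters` partition; genes must be in `universe`.
#' @param universe character vector of background genes.
#' @param p_cut screening p-value threshold (no multiple-testing correction,
#'   matching the original screen; set `bh = TRUE` for Benjamini-Hochberg).
#' @param min_genes minimum cluster genes per kept term.
#' @param bh apply Benjamini-Hochberg correction per cluster before the cut.
#' @return data.frame: `cluster_id`, `n_members`, `go_terms_enriched`,
#'   `go_terms_per_gene`, `go_mean_count_over_expected`.
#' @export
cluster_go_scores <- function(annot, cs, universe, p_cut = 0.01,
                              min_genes = 2L, bh = FALSE) {
  if (length(universe) == 0L) stop("empty gene universe")
  annot <- annot[annot$gene %in% universe, , drop = FALSE]
  term_genes <- split(annot$gene, annot$term)
  term_sizes <- vapply(term_genes, function(g) length(unique(g)), integer(1))
  n_univ <- length(unique(universe))
  do.call(rbind, lapply(split(names(cs), cs), function(members) {
    k <- length(members)
    genes_ann <- intersect(members, annot$gene)
    if (length(genes_ann) == 0L)
      return(data.frame(cluster_id = cs[[members[1L]]], n_members = k,
                        go_terms_enriched = 0L, go_terms_per_gene = 0,
                        go_mean_count_over_expected = NA_real_))
    counts <- vapply(term_genes, function(g)
      length(intersect(unique(g), members)), integer(1))
    present <- counts > 0L
    p <- hypergeom_tail_p(counts[present], term_sizes[present], n_univ, k)
    if (bh) p <- stats::p.adjust(p, method = "BH")
    keep <- p < p_cut & counts[present] >= min_genes
    n_terms <- sum(keep)
    expected <- term_sizes[present][keep] / n_univ * k
    ratio <- if (n_terms == 0L) 0 else
      mean(counts[present][keep] / expected)
    data.frame(cluster_id = cs[[members[1L]]], n_members = k,
               go_terms_enriched = n_terms,
               go_terms_per_gene = n_terms / k,
               go_mean_count_over_expected = ratio)
  }))
}

#' Random clusters mimicking an observed cluster-size distribution
#'
#' Generates `n_clusters` non-overlapping clusters whose sizes are sampled
#' with replacement from the template partition's cluster sizes and whose
#' members are sampled without replacement from the entity list; the
#' randomized sizes mimic the number of genes identified in the data-driven
#' clusters.  Deterministic given `seed`.
#'
#' @param entities character vector to draw members from.
#' @param template a `phospho_clusters` partition (size distribution source).
#' @param n_clusters number of random clusters (70 by default).
#' @param seed integer seed.
#' @return a `phospho_clusters` partition over the selected members.
#' @export
random_clusters <- function(entities, template, n_clusters = 70L, seed = 1L) {
  sizes_pool <- as.integer(table(template))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  sizes <- sample(sizes_pool, n_clusters, replace = TRUE)
  if (sum(sizes) > length(entities))
    stop("requested ", sum(sizes), " random-cluster members but only ",
         length(entities), " entities are available")
  members <- sample(entities, sum(sizes))
  labels <- rep(seq_len(n_clusters), times = sizes)
  names(labels) <- members
  cluster_set(labels, "random")
}

welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) return(NULL)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    d <- mean(x) - mean(y)
    return(list(t = 0, df = n1 + n2 - 2, p = if (d == 0) 1 else 0,
                mean_real = mean(x), mean_random = mean(y),
                n_real = n1, n_random = n2))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_real = mean(x), mean_random = mean(y),
       n_real = n1, n_random = n2)
}

#' Compare real cluster scores against randomized clusters
#'
#' Welch's two-sample two-sided t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom) per score metric, after dropping
#' missing values.  Metrics with fewer than two defined values on either
#' side are skipped with a warning.
#'
#' @param real,rand score data.frames sharing metric columns (as produced by
#'   the `cluster_*_scores` functions, possibly merged).
#' @param metrics metric column names to test (default: all shared numeric
#'   columns except ids and sizes).
#' @return list of class `cluster_eval_report`: `real`, `random`, `welch`
#'   (per-metric `t`, `df`, `p` and group means).
#' @export
compare_real_vs_random <- function(real, rand, metrics = NULL) {
  if (is.null(metrics)) {
    shared <- intersect(names(real), names(rand))
    metrics <- setdiff(shared[vapply(real[shared], is.numeric, logical(1))],
                       c("cluster_id", "n_members"))
  }
  welch <- list()
  for (metric in metrics) {
    res <- welch_t(real[[metric]], rand[[metric]])
    if (is.null(res)) {
      warning("metric '", metric,
              "' skipped: fewer than 2 defined values on one side")
      next
    }
    welch[[metric]] <- res
  }
  structure(list(real = real, random = rand, welch = welch),
            class = "cluster_eval_report")
}

#' @export
print.cluster_eval_report <- function(x, ...) {
  cat("cluster evaluation:", nrow(x$real), "real vs", nrow(x$random),
      "random clusters\n")
  for (metric in names(x$welch)) {
    w <- x$welch[[metric]]
    cat(sprintf("  %-28s real %9.3g  random %9.3g  Welch t %7.2f (df %5.1f)  p %.3g\n",
                metric, w$mean_real, w$mean_random, w$t, w$df, w$p))
  }
  invisible(x)
}

#' Score a partition on all evaluation metrics
#'
#' Convenience wrapper combining [cluster_internal_scores()],
#' [cluster_ppi_scores()] and [cluster_go_scores()] into one table.
#'
#' @inheritParams cluster_internal_scores
#' @inheritParams cluster_go_scores
#' @param g merged PPI igraph.
#' @export
score_clusters <- function(m, cs, g, annot, universe, p_cut = 0.01,
                           min_overlap = 3L) {
  internal <- cluster_internal_scores(m, cs, min_overlap)
  ppi <- cluster_ppi_scores(g, cs)
  go <- cluster_go_scores(annot, cs, universe, p_cut)
  out <- merge(merge(internal, ppi[c("cluster_id", "ppi_edges",
                                     "ppi_edge_weight")], by = "cluster_id"),
               go[setdiff(names(go), "n_members")], by = "cluster_id")
  out[order(out$cluster_id), ]
}
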