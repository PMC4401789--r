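#' Embed a dissimilarity matrix with t-SNE
#'
#' Runs t-distributed stochastic neighbor embedding directly on the
#' precomputed dissimilarity matrix (no re-derivation from raw data) to place
#' each entity at a 2- or 3-dimensional point such that statistically similar
#' entities are nearby.  The run is fully deterministic given `seed`.
#'
#' @param d a complete `phospho_dissim` (no missing values).
#' @param dims 2 or 3 (default 3).
#' @param perplexity target perplexity; default `min(30, (n - 1) / 3)`.
#' @param seed integer seed (mandatory in pipeline runs).
#' @param max_iter gradient-descent iterations.
#' @return a `phospho_embedding`: list with `entities`, `coords`
#'   (n x dims matrix), `source_kind`, `seed`.
#' @export
embed_tsne <- function(d, dims = 3L, perplexity = NULL, seed = 1L,
                       max_iter = 1000L) {
  stopifnot(dims %in% c(2L, 3L))
  n <- nrow(d)
  if (n < 5L) stop("too few points to embed (need >= 5)")
  if (is.null(perplexity)) perplexity <- max(3, min(30, (n - 1) / 3))
  coords <- tsne_precomputed(unclass(d), dims = dims, perplexity = perplexity,
                             seed = seed, max_iter = max_iter)
  rownames(coords) <- rownames(d)
  structure(list(entities = rownames(d), coords = coords,
                 source_kind = attr(d, "kind"), seed = seed),
            class = "phospho_embedding")
}

#' @export
print.phospho_embedding <- function(x, ...) {
  cat(sprintf("phospho_embedding (%s): %d entities in %d-D, seed %s\n",
              x$source_kind, length(x$entities), ncol(x$coords),
              format(x$seed)))
  invisible(x)
}

#' Construct a cluster partition
#'
#' @param labels named integer vector: cluster id per entity (a partition).
#' @param source_kind the dissimilarity kind the partition came from.
#' @export
cluster_set <- function(labels, source_kind = NA_character_) {
  stopifnot(!is.null(names(labels)), !anyNA(labels))
  structure(as.integer(labels), names = names(labels),
            source_kind = source_kind, class = "phospho_clusters")
}

#' @export
print.phospho_clusters <- function(x, ...) {
  cat(sprintf("phospho_clusters (%s): %d entities in %d clusters\n",
              attr(x, "source_kind"), length(x), length(unique(x))))
  invisible(x)
}

#' Extract clusters by the minimum-spanning-tree single-linkage rule
#'
#' Builds the Euclidean minimum spanning tree over the embedded coordinates,
#' removes the `k - 1` largest-weight MST edges (ties broken by lexicographic
#' edge-endpoint order) and reports the resulting connected components as
#' clusters.  This is equivalent to cutting a single-linkage dendrogram into
#' `k` groups.
#'
#' @param e a `phospho_embedding`, or a coordinate matrix with rownames.
#' @param k number of clusters, `1 <= k <= n`.
#' @return a `phospho_clusters` named integer vector (a partition).
#' @export
mst_single_linkage <- function(e, k) {
  coords <- if (inherits(e, "phospho_embedding")) e$coords else as.matrix(e)
  kind <- if (inherits(e, "phospho_embedding")) e$source_kind else NA_character_
  n <- nrow(coords)
  if (k < 1L || k > n) stop("k must lie in [1, n]")
  g <- igraph::graph_from_adjacency_matrix(
    as.matrix(stats::dist(coords)), mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(g, algorithm = "prim")
  if (k > 1L) {
    el <- igraph::as_edgelist(mst)
    w <- igraph::E(mst)$weight
    a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
    drop <- order(-w, a, b)[seq_len(k - 1L)]
    mst <- igraph::delete_edges(mst, drop)
  }
  comp <- igraph::components(mst)$membership
  cluster_set(comp[rownames(coords)], kind)
}

#' Choose the cluster count from a target range
#'
#' The analysis convention is 75-80 clusters at full dataset scale; the cut
#' count is taken as the midpoint of the target range (77 by default),
#' clamped to be valid for the embedding at hand.
#'
#' @param e a `phospho_embedding`.
#' @param target_range integer length-2 range of desired cluster counts.
#' @return a `phospho_clusters` partition with `floor(mean(target_range))`
#'   clusters.
#' @export
choose_k_by_target <- function(e, target_range = c(75L, 80L)) {
  k <- floor(mean(target_range))
  n <- length(e$entities)
  if (k > n) stop("target cluster count ", k, " exceeds entity count ", n)
  mst_single_linkage(e, k)
}

#' Bundle cluster sets from the three dissimilarity representations
#'
#' @param ... named `phospho_clusters` (typically `euclidean`, `spearman`,
#'   `sed`), all over the identical entity set.
#' @return a `phospho_cluster_collection` (named list).
#' @export
cluster_collection <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "phospho_clusters")) sets <- sets[[1]]
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("cluster sets must be named by their dissimilarity kind")
  ents <- lapply(sets, function(s) sort(names(s)))
  if (length(unique(ents)) != 1L)
    stop("all cluster sets must cover the identical entity list")
  structure(sets, class = "phospho_cluster_collection")
}

#' Write embedding / cluster tables
#'
#' @param e a `phospho_embedding`.
#' @param path output TSV path.
#' @rdname embed_io
#' @export
write_embedding <- function(e, path) {
  df <- data.frame(entity = e$entities, e$coords)
  names(df)[-1] <- c("x", "y", "z")[seq_len(ncol(e$coords))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param cc a `phospho_cluster_collection`.
#' @rdname embed_io
#' @export
write_clusters <- function(cc, path) {
  df <- do.call(rbind, lapply(names(cc), function(kind)
    data.frame(entity = names(cc[[kind]]), kind = kind,
               cluster_id = as.integer(cc[[kind]]))))
  df <- df[order(df$kind, df$cluster_id, df$entity), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
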