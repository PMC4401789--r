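#' Merge protein-protein interaction sources into one annotated graph
#'
#' Edge tables (columns `a`, `b`, `weight`, optional `source`) from databases
#' such as STRING, GeneMANIA or kinase-substrate sets are unioned.  Edges are
#' canonicalized to lexicographic endpoint order; duplicate pairs are merged
#' with combined weight (sum by default, the combined weight acting as
#' strength of evidence; `"max"` optionally) and concatenated provenance.
#'
#' @param sources list of edge data.frames.
#' @param combine `"sum"` (default) or `"max"` weight combination.
#' @return an undirected igraph with edge attributes `weight`, `provenance`,
#'   `type = "ppi"`.
#' @export
merge_ppi <- function(sources, combine = c("sum", "max")) {
  combine <- match.arg(combine)
  if (length(sources) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  tabs <- lapply(seq_along(sources), function(i) {
    s <- as.data.frame(sources[[i]])
    if (!all(c("a", "b", "weight") %in% names(s)))
      names(s)[1:3] <- c("a", "b", "weight")
    if (any(s$weight < 0)) stop("negative PPI edge weights are not allowed")
    if (is.null(s$source)) s$source <- paste0("source", i)
    s[c("a", "b", "weight", "source")]
  })
  edges <- do.call(rbind, tabs)
  if (nrow(edges) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  a <- pmin(edges$a, edges$b); b <- pmax(edges$a, edges$b)
  key <- paste(a, b, sep = "\r")
  keep <- a != b                      # no self-loops
  agg_w <- tapply(edges$weight[keep], key[keep],
                  if (combine == "sum") sum else max)
  agg_src <- tapply(edges$source[keep], key[keep],
                    function(s) paste(unique(s), collapse = ";"))
  ord <- sort(names(agg_w))
  parts <- strsplit(ord, "\r", fixed = TRUE)
  el <- data.frame(a = vapply(parts, `[`, "", 1L),
                   b = vapply(parts, `[`, "", 2L),
                   weight = as.numeric(agg_w[ord]),
                   provenance = as.character(agg_src[ord]),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::E(g)$type <- "ppi"
  g
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Pairs of entities that co-cluster across embeddings
#'
#' Inclusive mode returns pairs co-clustered in at least one of the listed
#' cluster sets (union); exclusive mode (the "hard" filter) returns pairs
#' co-clustered in all of them (intersection).  The co-cluster multiplicity
#' (in how many of the listed embeddings the pair co-clusters, 1-3) is
#' reported alongside.
#'
#' @param cc a `phospho_cluster_collection`.
#' @param mode `"inclusive"` or `"exclusive"`.
#' @param kinds which cluster sets to use (default: all in `cc`).
#' @return data.frame with columns `a`, `b` (lexicographic), `multiplicity`.
#' @export
cocluster_pairs <- function(cc, mode = c("inclusive", "exclusive"),
                            kinds = names(cc)) {
  mode <- match.arg(mode)
  if (length(kinds) == 0L) stop("at least one cluster-set kind is required")
  if (!all(kinds %in% names(cc)))
    stop("unknown cluster-set kind(s): ",
         paste(setdiff(kinds, names(cc)), collapse = ", "))
  keys <- unlist(lapply(kinds, function(kind) {
    cs <- cc[[kind]]
    unlist(lapply(split(names(cs), cs), function(members) {
      if (length(members) < 2L) return(character(0))
      members <- sort(members)
      p <- utils::combn(members, 2L)
      paste(p[1L, ], p[2L, ], sep = "\r")
    }), use.names = FALSE)
  }))
  if (length(keys) == 0L)
    return(data.frame(a = character(0), b = character(0),
                      multiplicity = integer(0)))
  tab <- table(keys)
  if (mode == "exclusive") tab <- tab[tab == length(kinds)]
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(a = vapply(parts, `[`, "", 1L),
                    b = vapply(parts, `[`, "", 2L),
                    multiplicity = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$a, out$b), , drop = FALSE]
}

#' Cluster-filtered network (CFN)
#'
#' Restricts the merged PPI graph to edges whose two endpoints co-clustered;
#' proteins left without any within-cluster interaction edge are dropped.
#'
#' @param ppi merged PPI igraph (see [merge_ppi()]).
#' @param pairs co-cluster pair data.frame (see [cocluster_pairs()]).
#' @return the filtered igraph.
#' @export
build_cfn <- function(ppi, pairs) {
  if (igraph::ecount(ppi) == 0L || nrow(pairs) == 0L) {
    g <- igraph::delete_edges(ppi, igraph::E(ppi))
    return(igraph::delete_vertices(g, igraph::V(g)))
  }
  el <- igraph::as_edgelist(ppi)
  keep <- pair_key(el[, 1L], el[, 2L]) %in% pair_key(pairs$a, pairs$b)
  g <- igraph::subgraph_from_edges(ppi, which(keep), delete.vertices = TRUE)
  g
}

#' Negative correlation edge layout transform
#'
#' Negative correlation edges are transformed to `exp(20 * rho)` so that an
#' edge-weighted spring-embedded layout places anti-correlated nodes far
#' apart; the transform is strictly increasing on `rho < 0` with values in
#' `(0, 1)`.
#'
#' @param rho negative Spearman correlation(s).
#' @export
transform_negative_edge <- function(rho) {
  if (any(rho >= 0)) stop("transform_negative_edge requires rho < 0")
  exp(20 * rho)
}

#' Co-cluster correlation network (CCCN)
#'
#' Connects co-clustered entities whose Spearman correlation passes the
#' absolute-value threshold (>= 0.5 by default).  Positive edges carry the
#' correlation as weight; negative edges carry the spring-layout weight
#' `exp(20 * rho)`.  Edge thickness is proportional to `|rho|` times the
#' number of embeddings in which the pair co-clustered.  Node attributes
#' record the total signed phosphorylation signal and a node class
#' (`activating` / `inhibitory`) used for colouring.
#'
#' @param m the (unnormalized) [phospho_matrix()] the clusters came from.
#' @param pairs co-cluster pairs with multiplicity.
#' @param rho_threshold minimum `|rho|`, in `(0, 1]`.
#' @param min_overlap minimum pairwise-complete observations for a defined rho.
#' @return an igraph with edge attributes `rho`, `sign`, `weight`,
#'   `thickness`, `type = "correlation"`.
#' @export
build_cccn <- function(m, pairs, rho_threshold = 0.5, min_overlap = 3L) {
  stopifnot(rho_threshold > 0, rho_threshold <= 1)
  pairs <- pairs[pairs$a %in% rownames(m) & pairs$b %in% rownames(m), ,
                 drop = FALSE]
  if (nrow(pairs)) {
    rho <- vapply(seq_len(nrow(pairs)), function(i) {
      x <- m[pairs$a[i], ]; y <- m[pairs$b[i], ]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_overlap) return(NA_real_)
      suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
    }, numeric(1))
    keep <- !is.na(rho) & abs(rho) >= rho_threshold
    pairs <- pairs[keep, , drop = FALSE]
    rho <- rho[keep]
  } else rho <- numeric(0)
  if (nrow(pairs) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  el <- data.frame(a = pairs$a, b = pairs$b, rho = rho,
                   sign = ifelse(rho >= 0, "+", "-"),
                   weight = ifelse(rho >= 0, rho,
                                   transform_negative_edge(pmin(rho, -1e-12))),
                   thickness = abs(rho) * pairs$multiplicity,
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::E(g)$type <- "correlation"
  total <- rowSums(m[igraph::V(g)$name, , drop = FALSE], na.rm = TRUE)
  igraph::V(g)$total_phospho <- as.numeric(total)
  igraph::V(g)$node_class <- ifelse(total < 0, "inhibitory", "activating")
  g
}

#' Whole-network statistics
#'
#' Global clustering coefficient (average of local transitivities, isolated
#' or degree-1 nodes counted as 0), diameter and mean shortest-path length on
#' the largest connected component, and a scale-free power-law fit: ordinary
#' least squares of `log(count)` on `log(degree)` over the degree
#' distribution, reported both for all degrees and for degrees above
#' `degree_min_for_fit` (mirroring the convention of reporting the fit with
#' and without the low-degree regime).
#'
#' @param g an igraph.
#' @param degree_min_for_fit low-degree cutoff for the second fit.
#' @return a list of class `network_stats`.
#' @export
network_stats <- function(g, degree_min_for_fit = 10L) {
  if (igraph::vcount(g) == 0L) stop("network_stats on an empty graph")
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  fit <- function(min_deg) {
    deg <- igraph::degree(g)
    tab <- table(deg[deg > min_deg & deg > 0])
    d <- as.numeric(names(tab)); cnt <- as.numeric(tab)
    if (length(d) < 3L) return(c(alpha = NA_real_, r2 = NA_real_))
    lmfit <- stats::lm(log(cnt) ~ log(d))
    c(alpha = -unname(stats::coef(lmfit)[2L]),
      r2 = summary(lmfit)$r.squared)
  }
  all_fit <- fit(0L); tail_fit <- fit(degree_min_for_fit)
  structure(list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    clustering_coefficient = igraph::transitivity(
      g, type = "localaverage", isolates = "zero"),
    diameter = igraph::diameter(giant, weights = NA),
    mean_path_length = igraph::mean_distance(giant, weights = NA),
    powerlaw_alpha = all_fit[["alpha"]], powerlaw_r2 = all_fit[["r2"]],
    powerlaw_alpha_tail = tail_fit[["alpha"]],
    powerlaw_r2_tail = tail_fit[["r2"]],
    degree_min_for_fit = degree_min_for_fit), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    paste0("network: %d nodes, %d edges\n",
           "clustering coefficient %.3f; diameter %d; mean path %.2f\n",
           "power law alpha %.3f (R2 %.3f); degrees > %d: alpha %.3f (R2 %.3f)\n"),
    x$n_nodes, x$n_edges, x$clustering_coefficient, x$diameter,
    x$mean_path_length, x$powerlaw_alpha, x$powerlaw_r2,
    x$degree_min_for_fit, x$powerlaw_alpha_tail, x$powerlaw_r2_tail))
  invisible(x)
}

#' Annotate a subnetwork with fraction-enrichment attributes
#'
#' Restricts the graph to nodes with an enrichment value and sets display
#' attributes on a log scale: ratio 1 is neutral (green), ratios above 1
#' positive enrichment (yellow, larger nodes), below 1 de-enrichment (blue,
#' smaller nodes).
#'
#' @param g an igraph.
#' @param node_values named numeric vector of enrichment ratios (> 0).
#' @export
fraction_subnetwork <- function(g, node_values) {
  keep <- igraph::V(g)$name %in% names(node_values)[!is.na(node_values)]
  sub <- igraph::induced_subgraph(g, which(keep))
  v <- node_values[igraph::V(sub)$name]
  lg <- log2(v)
  igraph::V(sub)$enrichment <- as.numeric(v)
  igraph::V(sub)$size <- 20 * 2^pmax(pmin(lg, 3), -3)  # clamp 8x range
  igraph::V(sub)$color <- ifelse(lg > 0, "yellow",
                                 ifelse(lg < 0, "blue", "green"))
  sub
}

#' Export a graph as GraphML plus Cytoscape-style tables
#'
#' Writes `<prefix>.graphml`, a node-attribute TSV and an edge TSV that can
#' be imported into Cytoscape.
#'
#' @param g an igraph.
#' @param prefix output path prefix.
#' @return the GraphML path, invisibly.
#' @export
write_graph_outputs <- function(g, prefix) {
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(graphml)
}
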