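# Shared fixtures and independent oracles for the test suite.

# Build peptide records directly (same columns as read_peptide_table output).
make_records <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    r <- utils::modifyList(list(peptide = "AAAAAAAyAAAAAAA", genes = "GENE",
                                sites = "GENE 100", sample = "S1",
                                intensity = 1, regulatory = "unknown",
                                ox_met = FALSE), r)
    data.frame(r, stringsAsFactors = FALSE)
  }))
  df[c("peptide", "genes", "sites", "sample", "intensity", "regulatory",
       "ox_met")]
}

# Small matrix with dimnames; body given row-wise.
mat <- function(body, nrow, entities = NULL, samples = NULL) {
  m <- matrix(body, nrow = nrow, byrow = TRUE)
  rownames(m) <- entities %||% paste0("E", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

pm <- function(body, nrow, level = "protein", ...)
  phospho_matrix(mat(body, nrow, ...), level)

# Bare numeric matrix from a dissimilarity object (drop class + metadata).
strip_dissim <- function(d) {
  a <- unclass(d)
  attributes(a) <- attributes(a)[c("dim", "dimnames")]
  a
}

# --- independent oracles ----------------------------------------------------

# NA-aware Euclidean, double loop over pairs (rescale by P/p).
oracle_euclidean <- function(m, min_overlap = 3) {
  n <- nrow(m); P <- ncol(m)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    p <- sum(ok)
    d[i, j] <- if (p == 0) NA_real_ else
      sqrt((P / p) * sum((m[i, ok] - m[j, ok])^2))
  }
  mx <- max(d[pair_overlap_oracle(m) >= min_overlap], na.rm = TRUE)
  d[pair_overlap_oracle(m) < min_overlap | is.na(d)] <- mx
  diag(d) <- 0
  d
}

pair_overlap_oracle <- function(m) {
  n <- nrow(m)
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    ov[i, j] <- sum(!is.na(m[i, ]) & !is.na(m[j, ]))
  ov
}

# Spearman via explicit average ranks + Pearson product-moment formula,
# double loop on pairwise-complete observations.
oracle_spearman <- function(m, min_overlap = 3) {
  n <- nrow(m)
  d <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    if (sum(ok) < min_overlap) next
    rx <- rank(m[i, ok]); ry <- rank(m[j, ok])
    sx <- rx - mean(rx); sy <- ry - mean(ry)
    den <- sqrt(sum(sx^2) * sum(sy^2))
    if (den == 0) next
    d[i, j] <- 1 - abs(sum(sx * sy) / den)
  }
  diag(d) <- 0
  d
}

# Hypergeometric upper-tail P[X >= q] by explicit binomial-coefficient sum.
oracle_hyper_tail <- function(q, n_ann, n_universe, k_cluster) {
  total <- choose(n_universe, k_cluster)
  sum(vapply(q:min(n_ann, k_cluster), function(x)
    choose(n_ann, x) * choose(n_universe - n_ann, k_cluster - x),
    numeric(1))) / total
}

# Random matrix with planted missingness.
random_na_matrix <- function(n, p, na_frac, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("E", seq_len(n)), paste0("S", seq_len(p))))
  mask <- sample(length(m), round(na_frac * length(m)))
  m[mask] <- NA_real_
  m
}

# Canonical small simulation reused by several module tests (kept small so
# each file stays fast; the full-scale world is exercised in the acceptance
# suite).
small_sim <- function(seed = 1) {
  simulate_phospho(sim_config(n_proteins = 60, n_samples = 12,
                              n_planted_clusters = 4, cluster_size = 5,
                              seed = seed))
}
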