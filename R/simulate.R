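#' Configuration for the synthetic phosphoproteomics world
#'
#' The generator emulates the statistical structure the pipeline assumes: a
#' reproducibly quantified "core" of proteins organized in planted
#' co-phosphorylation clusters, and a long tail of sporadically detected
#' proteins, as is typical of data-dependent-acquisition phosphoproteomics.
#' Cluster members share a switch-like latent per-sample profile on the
#' log-intensity scale (each cluster strongly activated in a random subset
#' of samples, as signaling pathways are) with additive Gaussian noise whose
#' sd is calibrated empirically at generation time so the pairwise Spearman
#' correlation within clusters matches `within_cluster_rho`.  Intensities are log-normal; missingness is
#' missing-completely-at-random per (protein, sample) cell at `missing_rate`
#' for core proteins and `background_missing_rate` for the sporadic tail
#' (an intensity-dependent left-censoring mode is also available, since real
#' MS missingness is abundance-biased).  A fraction of peptides carries a
#' conserved sequence shared with a second protein (ambiguous assignment), a
#' fraction is annotated inhibitory, PPI edges are Bernoulli with enriched
#' within-cluster probability, and GO terms are assigned predominantly
#' within planted clusters over a random background annotation.
#'
#' @param n_proteins total proteins (core + sporadic tail).
#' @param n_samples samples (cell lines / treatments / fractions).
#' @param n_planted_clusters number of planted co-phosphorylation clusters.
#' @param cluster_size members per planted cluster.
#' @param within_cluster_rho target within-cluster Spearman correlation.
#' @param missing_rate cell-level missingness of core proteins.
#' @param background_missing_rate missingness of the sporadic tail.
#' @param missing_mode `"mcar"` or `"censor"` (left-censored by intensity).
#' @param intensity_meanlog,intensity_sdlog log-normal intensity parameters.
#' @param frac_ambiguous_peptides fraction of peptides shared with a second
#'   protein (conserved sequence).
#' @param frac_inhibitory fraction of proteins carrying an inhibitory site.
#' @param ppi_within_prob,ppi_between_prob Bernoulli PPI edge probabilities
#'   within planted clusters and elsewhere.
#' @param go_terms_per_cluster planted GO terms per cluster.
#' @param go_background_terms size of the background GO term pool.
#' @param go_background_per_gene background terms drawn per gene.
#' @param seed integer seed; the whole emission is deterministic given it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_proteins = 400L, n_samples = 16L,
                       n_planted_clusters = 10L, cluster_size = 5L,
                       within_cluster_rho = 0.9, missing_rate = 0.2,
                       background_missing_rate = 0.8,
                       missing_mode = c("mcar", "censor"),
                       intensity_meanlog = 18, intensity_sdlog = 1,
                       frac_ambiguous_peptides = 0.05,
                       frac_inhibitory = 0.1,
                       ppi_within_prob = 0.3, ppi_between_prob = 0.01,
                       go_terms_per_cluster = 3L, go_background_terms = 60L,
                       go_background_per_gene = 2L, seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_samples = as.integer(n_samples),
              n_planted_clusters = as.integer(n_planted_clusters),
              cluster_size = as.integer(cluster_size),
              within_cluster_rho = within_cluster_rho,
              missing_rate = missing_rate,
              background_missing_rate = background_missing_rate,
              missing_mode = match.arg(missing_mode),
              intensity_meanlog = intensity_meanlog,
              intensity_sdlog = intensity_sdlog,
              frac_ambiguous_peptides = frac_ambiguous_peptides,
              frac_inhibitory = frac_inhibitory,
              ppi_within_prob = ppi_within_prob,
              ppi_between_prob = ppi_between_prob,
              go_terms_per_cluster = as.integer(go_terms_per_cluster),
              go_background_terms = as.integer(go_background_terms),
              go_background_per_gene = as.integer(go_background_per_gene),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_proteins > 0, n_samples >= 4,
              n_planted_clusters >= 1, cluster_size >= 2,
              within_cluster_rho > 0, within_cluster_rho < 1,
              missing_rate >= 0, missing_rate < 1,
              background_missing_rate >= 0, background_missing_rate < 1,
              frac_ambiguous_peptides >= 0, frac_ambiguous_peptides <= 1,
              frac_inhibitory >= 0, frac_inhibitory <= 1,
              ppi_within_prob >= 0, ppi_within_prob <= 1,
              ppi_between_prob >= 0, ppi_between_prob <= 1,
              ppi_within_prob > ppi_between_prob)
    if (n_planted_clusters * cluster_size > n_proteins)
      stop("planted clusters do not fit: ", n_planted_clusters, " x ",
           cluster_size, " > ", n_proteins, " proteins")
  })
  structure(cfg, class = "sim_config")
}

# Monte-Carlo calibration of the member-noise sd: for the latent profiles at
# hand, find sigma such that the expected pairwise Spearman correlation of
# two members (latent + sigma * noise) matches the target.  Monotone in
# sigma, so a bisection on an empirical estimate suffices.
calibrate_noise_sd <- function(Z, W, target_rho, n_rep = 120L) {
  est <- function(sigma) {
    mean(vapply(seq_len(n_rep), function(i) {
      row <- (i - 1L) %% nrow(Z) + 1L
      z <- Z[row, ]; w <- W[row, ]
      u <- z + sigma * w * stats::rnorm(length(z))
      v <- z + sigma * w * stats::rnorm(length(z))
      stats::cor(u, v, method = "spearman")
    }, numeric(1)))
  }
  lo <- 0.01; hi <- 3
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    if (est(mid) > target_rho) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

random_peptide_seq <- function(n) {
  aa <- c("A", "D", "E", "F", "G", "I", "K", "L", "N", "P", "Q", "R", "S",
          "T", "V")
  vapply(seq_len(n), function(i) {
    left <- paste(sample(aa, 7, replace = TRUE), collapse = "")
    right <- paste(sample(aa, 7, replace = TRUE), collapse = "")
    paste0(left, "y", right)  # lower-case y marks the phosphosite
  }, character(1))
}

#' Simulate a phosphoproteomic dataset with planted structure
#'
#' Emits exactly the tables the ingest, network and evaluation modules
#' consume (peptide table, PPI edge table, GO annotation table) plus the
#' ground truth needed to score recovery.  Fully deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `peptides`, `ppi`, `go` (data.frames) and `truth`
#'   (planted labels, PPI edges with a `within` flag, planted GO
#'   assignments, ambiguous-peptide truth, and the config).
#' @export
simulate_phospho <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  n <- cfg$n_proteins; S <- cfg$n_samples
  k <- cfg$n_planted_clusters; csize <- cfg$cluster_size
  genes <- sprintf("P%03d", seq_len(n))
  samples <- sprintf("S%02d", seq_len(S))
  n_core <- k * csize
  labels <- rep(seq_len(k), each = csize)
  names(labels) <- genes[seq_len(n_core)]
  background <- genes[setdiff(seq_len(n), seq_len(n_core))]

  # Latent log-scale cluster profiles are switch-like, as signaling is: each
  # cluster is strongly activated in a random subset of samples on top of
  # baseline variation, which is what makes co-phosphorylation clusters
  # separable by magnitude (Euclidean) as well as by rank (Spearman).
  # Member profiles add Gaussian noise whose sd is calibrated empirically at
  # generation time so the within-cluster pairwise Spearman correlation hits
  # the configured target.
  # each cluster is activated in ~25% of the samples; activation sets are
  # drawn to overlap in at most one sample between clusters, so planted
  # clusters are well separated in both magnitude and rank space
  m_active <- max(2L, round(0.25 * S))
  active <- matrix(FALSE, k, S)
  chosen <- list()
  for (c in seq_len(k)) {
    best <- NULL; best_ov <- Inf
    for (try in seq_len(200L)) {
      cand <- sample(S, m_active)
      ov <- if (length(chosen) == 0L) 0L else
        max(vapply(chosen, function(p) length(intersect(p, cand)), integer(1)))
      if (ov < best_ov) { best <- cand; best_ov <- ov }
      if (ov <= 1L) break
    }
    chosen[[c]] <- best
    active[c, best] <- TRUE
  }
  Z <- 2.5 * active + matrix(stats::rnorm(k * S), k, S)
  # measurement noise is heteroscedastic, as MS1 quantification is: strong
  # (activated) signals are measured with small relative error, weak
  # baseline signals with large error
  W <- ifelse(active, 0.15, 1)
  sigma_n <- calibrate_noise_sd(Z, W, cfg$within_cluster_rho)
  X <- matrix(stats::rnorm(n * S), n, S)
  X[seq_len(n_core), ] <- Z[labels, , drop = FALSE] +
    sigma_n * W[labels, , drop = FALSE] * X[seq_len(n_core), , drop = FALSE]
  intensity <- exp(cfg$intensity_meanlog + cfg$intensity_sdlog * X)
  dimnames(intensity) <- list(genes, samples)

  # per-protein peptide complement (1-4 peptides, fixed shares across samples)
  n_pep <- sample(1:4, n, replace = TRUE)
  inhibitory_protein <- stats::runif(n) < cfg$frac_inhibitory
  pep <- do.call(rbind, lapply(seq_len(n), function(i) {
    np <- n_pep[i]
    w <- stats::rgamma(np, 2); w <- w / sum(w)
    inh <- rep(FALSE, np)
    if (inhibitory_protein[i]) {
      u <- stats::runif(1, 0.05, 0.3)   # inhibitory share, keeps totals > 0
      w <- c(w * (1 - u), u)
      inh <- c(inh, TRUE)
      np <- np + 1L
    }
    data.frame(protein = genes[i], pep_idx = seq_len(np), share = w,
               inhibitory = inh, stringsAsFactors = FALSE)
  }))
  pep$peptide <- random_peptide_seq(nrow(pep))
  pep$pos <- sample(50:1500, nrow(pep), replace = TRUE)
  pep$genes <- pep$protein
  pep$sites <- paste(pep$protein, pep$pos)
  # conserved sequences shared with a second protein
  amb <- stats::runif(nrow(pep)) < cfg$frac_ambiguous_peptides
  partner_idx <- sapply(match(pep$protein, genes),
                        function(i) sample(setdiff(seq_len(n), i), 1L))
  pep$genes[amb] <- paste(pep$protein[amb], genes[partner_idx[amb]], sep = ";")
  pep$sites[amb] <- paste0(pep$sites[amb], "; ", genes[partner_idx[amb]], " ",
                           sample(50:1500, sum(amb), replace = TRUE))

  # cell-level missingness mask (TRUE = observed)
  rate <- ifelse(genes %in% names(labels), cfg$missing_rate,
                 cfg$background_missing_rate)
  if (cfg$missing_mode == "mcar") {
    observed <- matrix(stats::runif(n * S), n, S) >= rate
  } else {
    # left-censoring: low-intensity cells are preferentially masked; the
    # per-protein rate is preserved on average
    pmiss <- t(apply(intensity, 1L, function(v) {
      q <- rank(v) / (S + 1)
      p <- (1 - q)^2
      p / mean(p)
    })) * rate
    observed <- matrix(stats::runif(n * S), n, S) >= pmin(pmiss, 0.95)
  }
  dimnames(observed) <- dimnames(intensity)

  # emit peptide rows for observed cells; ~10% of peptides appear as an
  # oxidized-methionine pair splitting the same signal 70/30
  ox_pair <- stats::runif(nrow(pep)) < 0.1
  rows <- lapply(seq_len(nrow(pep)), function(j) {
    p <- pep[j, ]
    obs <- which(observed[p$protein, ])
    if (!length(obs)) return(NULL)
    amount <- intensity[p$protein, obs] * p$share *
      exp(stats::rnorm(length(obs), 0, 0.05))
    base <- data.frame(
      peptide = p$peptide, genes = p$genes, sites = p$sites,
      sample = samples[obs], intensity = amount,
      regulatory = if (p$inhibitory) "inhibitory" else
        sample(c("activating", "unknown"), 1L),
      ox_met = FALSE, stringsAsFactors = FALSE)
    if (ox_pair[j]) {
      ox <- base
      ox$intensity <- base$intensity * 0.3
      ox$ox_met <- TRUE
      base$intensity <- base$intensity * 0.7
      base <- rbind(base, ox)
    }
    base
  })
  peptides <- do.call(rbind, rows)
  rownames(peptides) <- NULL

  # PPI: Bernoulli edges, enriched within planted clusters
  pairs <- t(utils::combn(genes, 2L))
  same <- unname(!is.na(labels[pairs[, 1L]]) & !is.na(labels[pairs[, 2L]]) &
                   labels[pairs[, 1L]] == labels[pairs[, 2L]])
  same[is.na(same)] <- FALSE
  prob <- ifelse(same, cfg$ppi_within_prob, cfg$ppi_between_prob)
  hit <- stats::runif(nrow(pairs)) < prob
  ppi <- data.frame(a = pairs[hit, 1L], b = pairs[hit, 2L],
                    weight = round(stats::runif(sum(hit), 0.2, 1), 3),
                    source = sample(c("string", "genemania"), sum(hit),
                                    replace = TRUE),
                    stringsAsFactors = FALSE)

  # GO: planted per-cluster terms covering most members, plus a random
  # background annotation giving every gene a few generic terms
  planted_go <- do.call(rbind, lapply(seq_len(k), function(c) {
    members <- names(labels)[labels == c]
    do.call(rbind, lapply(seq_len(cfg$go_terms_per_cluster), function(t) {
      term <- sprintf("GO:C%02dT%d", c, t)
      covered <- members[stats::runif(length(members)) < 0.8]
      if (length(covered) < 2L) covered <- members[1:2]
      leak <- sample(setdiff(genes, members), sample(0:2, 1L))
      data.frame(gene = c(covered, leak), term = term,
                 stringsAsFactors = FALSE)
    }))
  }))
  bg_terms <- sprintf("GO:BG%03d", seq_len(cfg$go_background_terms))
  bg_go <- data.frame(
    gene = rep(genes, each = cfg$go_background_per_gene),
    term = unlist(lapply(genes, function(g)
      sample(bg_terms, cfg$go_background_per_gene))),
    stringsAsFactors = FALSE)
  go <- unique(rbind(planted_go, bg_go))
  rownames(go) <- NULL

  truth <- list(
    labels = labels, background = background,
    ppi = data.frame(a = pairs[hit, 1L], b = pairs[hit, 2L],
                     within = same[hit], stringsAsFactors = FALSE),
    go_planted = planted_go,
    ambiguous = data.frame(peptide = pep$peptide[amb],
                           true_gene = pep$protein[amb],
                           stringsAsFactors = FALSE),
    config = unclass(cfg))
  list(peptides = peptides, ppi = ppi, go = go, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits `peptides.tsv`, `ppi.tsv`, `go.tsv` (the dialects the ingest,
#' network and evaluation modules read) and `truth.json`.
#'
#' @param sim result of [simulate_phospho()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  out(sim$peptides, "peptides.tsv")
  out(sim$ppi, "ppi.tsv")
  out(sim$go, "go.tsv")
  truth <- sim$truth
  truth$labels <- as.list(truth$labels)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings.  If both vectors are
#' named, they are aligned on their common names first.
#'
#' @param a,b cluster label vectors.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 1L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Score recovery of planted structure
#'
#' Adjusted Rand index between recovered and planted cluster labels per
#' embedding kind (computed over the planted, core proteins present in each
#' clustering), and, when a CFN is supplied, the fraction of planted
#' within-cluster PPI edges it retains and the fraction of between-cluster
#' edges that leak through.
#'
#' @param truth `truth` component of [simulate_phospho()] output.
#' @param cc a `phospho_cluster_collection` of recovered partitions.
#' @param cfn optional CFN igraph.
#' @return list: `ari` (named per kind), and with `cfn`:
#'   `within_edge_retention`, `between_edge_retention`.
#' @export
truth_recovery_report <- function(truth, cc, cfn = NULL) {
  ari <- vapply(cc, function(cs)
    adjusted_rand_index(truth$labels, structure(as.integer(cs),
                                                names = names(cs))),
    numeric(1))
  out <- list(ari = ari)
  if (!is.null(cfn)) {
    cfn_keys <- if (igraph::ecount(cfn)) {
      el <- igraph::as_edgelist(cfn)
      pair_key(el[, 1L], el[, 2L])
    } else character(0)
    tk <- pair_key(truth$ppi$a, truth$ppi$b)
    within <- truth$ppi$within
    out$within_edge_retention <-
      if (any(within)) mean(tk[within] %in% cfn_keys) else NA_real_
    out$between_edge_retention <-
      if (any(!within)) mean(tk[!within] %in% cfn_keys) else NA_real_
  }
  out
}
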