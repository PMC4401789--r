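#' Dissimilarity representations of phosphorylation profiles
#'
#' Three representations of the statistical relationship between entity row
#' profiles are supported, all aware of missing values:
#' \describe{
#'   \item{euclidean}{NA-aware Euclidean distance.  For a pair observed in
#'     `p` of `P` samples, `d = sqrt((P/p) * sum over shared samples (x-y)^2)`,
#'     i.e. the partial sum is rescaled up proportionally.}
#'   \item{spearman}{one minus the absolute value of the Spearman rank
#'     correlation on pairwise-complete observations (average ranks for
#'     ties), so strongly anti-correlated profiles are also "similar".}
#'   \item{sed}{the hybrid Spearman-Euclidean dissimilarity: both inputs
#'     rescaled to `[0, 1]` by their maxima and averaged.}
#' }
#' Pairs with fewer than `min_overlap` shared observations cannot support a
#' statistic; they are imputed with the maximum observed dissimilarity
#' (Euclidean) or 1 (Spearman) so that the embedding receives a complete
#' matrix.
#'
#' @name dissimilarity
NULL

new_dissim <- function(values, kind, min_overlap) {
  stopifnot(isSymmetric(unname(values)))
  diag(values) <- 0
  structure(values, kind = kind, min_overlap = min_overlap,
            class = c("phospho_dissim", class(values)))
}

#' @export
print.phospho_dissim <- function(x, ...) {
  cat(sprintf("phospho_dissim (%s): %d entities, range [%.4g, %.4g]\n",
              attr(x, "kind"), nrow(x), min(x), max(x)))
  invisible(x)
}

pair_overlap <- function(obs) tcrossprod(obs * 1)

#' Scale samples by their standard deviations without centering
#'
#' Each sample column is divided by the standard deviation of its observed
#' (non-missing) values (`n - 1` denominator) so that all samples weigh
#' equally in distance calculations; values are not centered, preserving the
#' meaning of zero.  Missing cells stay missing.
#'
#' @param m a [phospho_matrix()] (or plain matrix with dimnames).
#' @return the scaled matrix, same class and dimnames.
#' @export
normalize_by_sample_sd <- function(m) {
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad))
    stop("sample(s) with zero or undefined standard deviation: ",
         paste(colnames(m)[bad], collapse = ", "))
  out <- sweep(m, 2L, sds, "/")
  if (inherits(m, "phospho_matrix")) phospho_matrix(out, attr(m, "level"))
  else out
}

#' NA-aware Euclidean dissimilarity between entity rows
#'
#' @param m normalized matrix, entities in rows.
#' @param min_overlap minimum shared observed samples for a pair; below it the
#'   pair is set to the maximum over valid pairs.
#' @param rescale if `TRUE` (default) partial sums are rescaled by `P/p`
#'   (the classical statistical-environment convention); if `FALSE` the raw
#'   partial sum of squares is used.
#' @return a `phospho_dissim` of kind `"euclidean"`.
#' @export
dissim_euclidean <- function(m, min_overlap = 3L, rescale = TRUE) {
  d <- as.matrix(stats::dist(m))            # implements the P/p rescale
  if (!rescale) {
    ov <- pair_overlap(!is.na(m))
    d <- d * sqrt(ov / ncol(m))
    d[ov == 0] <- NA_real_
  }
  ov <- pair_overlap(!is.na(m))
  invalid <- ov < min_overlap | !is.finite(d)
  diag(invalid) <- FALSE
  if (all(invalid[upper.tri(invalid)])) stop("no entity pair has sufficient overlap")
  mx <- max(d[!invalid], na.rm = TRUE)
  d[invalid] <- mx
  new_dissim(d, "euclidean", as.integer(min_overlap))
}

#' Spearman dissimilarity (1 - |rho|) between entity rows
#'
#' Rank correlations are computed on pairwise-complete observations with
#' average ranks for ties.  Pairs with insufficient overlap, or where either
#' profile is constant over the shared samples (undefined rho), get
#' dissimilarity 1.
#'
#' @inheritParams dissim_euclidean
#' @return a `phospho_dissim` of kind `"spearman"`.
#' @export
dissim_spearman <- function(m, min_overlap = 3L) {
  rho <- suppressWarnings(
    stats::cor(t(m), method = "spearman", use = "pairwise.complete.obs"))
  d <- 1 - abs(rho)
  ov <- pair_overlap(!is.na(m))
  d[ov < min_overlap | !is.finite(d)] <- 1
  d <- pmin(pmax(d, 0), 1)
  new_dissim(d, "spearman", as.integer(min_overlap))
}

#' Hybrid Spearman-Euclidean dissimilarity (SED)
#'
#' Equal-weight combination of the two representations: each input is scaled
#' to `[0, 1]` by division by its maximum and the two are averaged
#' elementwise.
#'
#' @param de Euclidean `phospho_dissim`.
#' @param ds Spearman `phospho_dissim` over the same entities in the same order.
#' @return a `phospho_dissim` of kind `"sed"`.
#' @export
dissim_sed <- function(de, ds) {
  if (attr(de, "kind") != "euclidean" || attr(ds, "kind") != "spearman")
    stop("dissim_sed expects (euclidean, spearman) inputs")
  if (!identical(rownames(de), rownames(ds)))
    stop("entity mismatch between Euclidean and Spearman inputs")
  scale01 <- function(x) { mx <- max(x); if (mx > 0) x / mx else x }
  new_dissim((scale01(unclass(de)) + scale01(unclass(ds))) / 2, "sed",
             max(attr(de, "min_overlap"), attr(ds, "min_overlap")))
}

#' Write / read a square dissimilarity matrix as TSV (+ sidecar JSON)
#'
#' The matrix goes to `path` with entity ids as row and column headers; kind
#' and minimum overlap are recorded in `<path>.json`.
#' @param d a `phospho_dissim`.
#' @param path file path.
#' @rdname dissim_io
#' @export
write_dissim <- function(d, path) {
  df <- data.frame(entity = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(kind = attr(d, "kind"), min_overlap = attr(d, "min_overlap")),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname dissim_io
#' @export
read_dissim <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  new_dissim(vals, meta$kind, as.integer(meta$min_overlap))
}
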