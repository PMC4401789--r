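#' Signed fold change between treatment and control
#'
#' Symmetric fold-change convention: `treatment/control` when treatment is at
#' least control, `-(control/treatment)` otherwise, so a halving is `-2`
#' rather than `0.5` and `|fold| >= 1` always.  Intensities are compared by
#' magnitude.  If either side is missing the result is missing; a zero on
#' either side leaves the ratio undefined (`NA`, with a warning).
#'
#' @param t,c treatment and control intensities (vectors recycle).
#' @return signed fold changes.
#' @export
fold_change <- function(t, c) {
  t <- abs(t); c <- abs(c)
  zero <- !is.na(t) & !is.na(c) & (t == 0 | c == 0)
  if (any(zero))
    warning(sum(zero), " fold change(s) undefined (zero intensity) -> NA")
  out <- ifelse(t >= c, t / c, -c / t)
  out[zero] <- NA_real_
  out
}

#' Keep fold changes exceeding a threshold
#'
#' Retains rows with `|fold| > threshold` (strictly: a change of exactly
#' twofold is dropped at the default threshold of 2).
#'
#' @param tbl data.frame with a `fold` column.
#' @param threshold magnitude threshold, `>= 1`.
#' @export
filter_twofold <- function(tbl, threshold = 2) {
  stopifnot(threshold >= 1)
  tbl[!is.na(tbl$fold) & abs(tbl$fold) > threshold, , drop = FALSE]
}

#' Enrichment of entities in an organelle fraction
#'
#' Per entity, the ratio of the mean absolute intensity over the fraction
#' samples (e.g. endosomes or detergent-resistant membranes) to the mean
#' over all background samples, ignoring missing values on both sides;
#' `NA` where either mean is undefined.
#'
#' @param m a [phospho_matrix()].
#' @param fraction_samples,background_samples disjoint sample id sets.
#' @return data.frame: `entity`, `ratio`.
#' @export
fraction_enrichment <- function(m, fraction_samples, background_samples) {
  if (length(intersect(fraction_samples, background_samples)))
    stop("fraction and background sample sets overlap")
  if (!length(fraction_samples) || !length(background_samples))
    stop("both sample sets must be non-empty")
  missing_s <- setdiff(c(fraction_samples, background_samples), colnames(m))
  if (length(missing_s))
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  num <- rowMeans(abs(m[, fraction_samples, drop = FALSE]), na.rm = TRUE)
  den <- rowMeans(abs(m[, background_samples, drop = FALSE]), na.rm = TRUE)
  ratio <- num / den
  ratio[!is.finite(ratio)] <- NA_real_
  data.frame(entity = rownames(m), ratio = as.numeric(ratio),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Order a matrix for heat-map rendering
#'
#' `magnitude` mode sorts rows and columns by descending total absolute
#' signal (most to least, left to right and top to bottom); `hclust` mode
#' orders rows by average-linkage hierarchical clustering on the NA-aware
#' Euclidean distance, so missing values are handled by the same rescaled
#' partial distances used elsewhere.  The render spec records the
#' blue-yellow diverging scale with black for missing cells.
#'
#' @param m matrix-like with dimnames.
#' @param sort_mode `"magnitude"` or `"hclust"`.
#' @param na_token token to use for missing cells on export.
#' @return list: `matrix` (reordered), `row_order`, `col_order`,
#'   `render_spec`.
#' @export
heatmap_export <- function(m, sort_mode = c("magnitude", "hclust"),
                           na_token = "NA") {
  sort_mode <- match.arg(sort_mode)
  m <- as.matrix(m)
  if (sort_mode == "magnitude") {
    row_order <- order(rowSums(abs(m), na.rm = TRUE), decreasing = TRUE)
    col_order <- order(colSums(abs(m), na.rm = TRUE), decreasing = TRUE)
  } else {
    if (nrow(m) > 2L) {
      hc <- stats::hclust(stats::dist(m), method = "average")
      row_order <- hc$order
    } else row_order <- seq_len(nrow(m))
    col_order <- seq_len(ncol(m))
  }
  list(matrix = m[row_order, col_order, drop = FALSE],
       row_order = rownames(m)[row_order],
       col_order = colnames(m)[col_order],
       render_spec = list(palette = "blue-yellow", diverging = TRUE,
                          na_color = "black", na_token = na_token,
                          sort_mode = sort_mode))
}
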