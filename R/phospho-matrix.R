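#' Signed phosphorylation intensity matrix
#'
#' A `phospho_matrix` is a plain numeric matrix of summed, signed MS1 peak
#' intensities with entities (proteins, `"GENE_i"` inhibitory aggregates, or
#' `"GENE POS"` phosphorylation sites) as rows and samples as columns.
#' Missing values are stored as `NA` and are semantically distinct from 0:
#' `NA` means the entity was not detected in that sample, not that its
#' phosphorylation was zero.
#'
#' @param values numeric matrix with rownames (entities) and colnames (samples).
#' @param level `"protein"` or `"site"`.
#' @return A numeric matrix of class `phospho_matrix` with a `level` attribute.
#' @export
phospho_matrix <- function(values, level = c("protein", "site")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("phospho_matrix requires entity rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate entity ids in phospho_matrix")
  storage.mode(values) <- "double"
  structure(values, level = level, class = c("phospho_matrix", class(values)))
}

#' @export
print.phospho_matrix <- function(x, ...) {
  cat(sprintf("phospho_matrix (%s level): %d entities x %d samples, %.1f%% NA\n",
              attr(x, "level"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Write / read a phosphorylation matrix as TSV
#'
#' Wide tab-separated text with entity ids in the first column, sample ids in
#' the header, and the literal token `NA` for missing cells.  `read` is the
#' exact inverse of `write`, including `NA` cells.
#'
#' @param m a [phospho_matrix()].
#' @param path file path.
#' @rdname matrix_io
#' @export
write_phospho_matrix <- function(m, path) {
  df <- data.frame(entity = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @param level matrix level recorded on read.
#' @rdname matrix_io
#' @export
read_phospho_matrix <- function(path, level = c("protein", "site")) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  phospho_matrix(vals, match.arg(level))
}

#' Export a matrix in long form
#'
#' One row per observed (entity, sample) cell; `NA` cells are kept so the
#' output is a faithful flat rendering of the matrix.
#' @inheritParams write_phospho_matrix
#' @export
write_phospho_long <- function(m, path) {
  long <- data.frame(
    entity = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    value  = as.vector(m), stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Drop sparsely quantified entities
#'
#' Shotgun phosphoproteomics tables carry a long tail of sporadically detected
#' entities.  Pairwise statistics on such rows rest on almost no shared
#' observations, so the embedding stages work on entities quantified in at
#' least `min_frac` of the samples (the evaluation stages keep the full
#' matrix).
#'
#' @param m a [phospho_matrix()].
#' @param min_frac minimum fraction of non-missing samples per entity.
#' @return the filtered `phospho_matrix`.
#' @export
filter_min_observed <- function(m, min_frac = 0.5) {
  stopifnot(min_frac >= 0, min_frac <= 1)
  keep <- rowMeans(!is.na(m)) >= min_frac
  phospho_matrix(m[keep, , drop = FALSE], attr(m, "level"))
}
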