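#' SRC-family kinases whose C-terminal inhibitory sites are tracked separately
#'
#' Each SRC-family kinase carries an activating loop tyrosine and a C-terminal
#' inhibitory tyrosine; peptides phosphorylated on the inhibitory site are
#' summed into a separate `"GENE_i"` entity (e.g. `FYN_i`) with negative sign
#' so that inhibitory phosphorylation can be distinguished from activation in
#' the same sample.
#' @export
SFK_GENES <- c("SRC", "FYN", "LYN", "YES1", "FRK")

REGULATORY_LEVELS <- c("activating", "inhibitory", "unknown")

#' Read a phosphopeptide quantification table
#'
#' Expects a delimited text table with header columns `peptide`, `genes`
#' (`;`-separated gene symbols, first name is the fallback assignment),
#' `sites` (`;`-separated `"GENE POS"` ids, parallel to `genes`), `sample`,
#' `intensity` (non-negative MS1 peak intensity), `regulatory`
#' (`activating`/`inhibitory`/`unknown`) and `ox_met` (logical, oxidized
#' methionine variant).  Rows whose intensity does not parse as a number are
#' dropped with a warning naming the offending row indices.
#'
#' @param path file path.
#' @param sep field separator; `NULL` guesses TSV for `.tsv`/`.txt`, CSV for `.csv`.
#' @return a data.frame of peptide records (one per retained row).
#' @export
read_peptide_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("peptide table not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  required <- c("peptide", "genes", "sites", "sample", "intensity",
                "regulatory", "ox_met")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("peptide table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("peptide table ", path, " contains a header but no rows")
    df$intensity <- numeric(0)
    df$ox_met <- logical(0)
    return(df[required])
  }
  intensity <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(is.na(intensity))
  if (length(bad)) {
    warning("dropping ", length(bad), " row(s) with non-numeric intensity: ",
            paste(utils::head(bad, 10L), collapse = ", "))
    df <- df[-bad, , drop = FALSE]
    intensity <- intensity[-bad]
  }
  if (any(intensity < 0)) stop("negative peak intensities are not allowed")
  df$intensity <- intensity
  df$ox_met <- as.logical(df$ox_met)
  bad_reg <- setdiff(unique(df$regulatory), REGULATORY_LEVELS)
  if (length(bad_reg))
    stop("unknown regulatory annotation(s): ", paste(bad_reg, collapse = ", "))
  rownames(df) <- NULL
  df[required]
}

split_field <- function(x) strsplit(x, ";[ ]*")

#' Resolve ambiguous peptide-to-protein assignment within one sample
#'
#' Conserved peptide sequences can match several proteins.  The exclusive rule
#' is: if any candidate protein is identified by a *different* peptide in the
#' same sample, the peptide is assigned to that protein (first such candidate
#' in the peptide's own gene order); otherwise the first listed name is used.
#' Unambiguous peptides map to their sole gene.
#'
#' @param records data.frame of peptide records (as from
#'   [read_peptide_table()]) all belonging to one sample.
#' @param sample optional sample id; if given, `records` is subset to it.
#' @return character vector of assigned gene symbols, one per record.
#' @export
assign_ambiguous <- function(records, sample = NULL) {
  if (!is.null(sample)) records <- records[records$sample == sample, ,
                                           drop = FALSE]
  if (length(unique(records$sample)) > 1L)
    stop("assign_ambiguous operates on records from a single sample")
  gene_lists <- split_field(records$genes)
  n <- nrow(records)
  assigned <- character(n)
  for (i in seq_len(n)) {
    cand <- gene_lists[[i]]
    if (length(cand) == 1L) { assigned[i] <- cand; next }
    # genes evidenced by a different peptide sequence in this sample
    seen <- unique(unlist(gene_lists[records$peptide != records$peptide[i]]))
    hit <- cand[cand %in% seen]
    assigned[i] <- if (length(hit)) hit[1L] else cand[1L]
  }
  assigned
}

signed_intensity <- function(records) {
  ifelse(records$regulatory == "inhibitory", -records$intensity,
         records$intensity)
}

#' Sum phosphopeptides into a protein-level signed intensity matrix
#'
#' Within each sample, ambiguous peptides are first assigned to a single
#' protein ([assign_ambiguous()]), then peak intensities are summed per
#' protein.  Peptides annotated as phosphorylated on inhibitory sites
#' contribute with negative sign; for the SRC-family kinases in `sfk_list`
#' those peptides are instead accumulated in a separate `"GENE_i"` entity
#' (always non-positive).  A (protein, sample) pair with no contributing
#' peptide is `NA`, never 0.
#'
#' @param records peptide record data.frame (all samples).
#' @param sfk_list genes whose inhibitory-site signal is tracked as `"GENE_i"`.
#' @return a protein-level [phospho_matrix()].
#' @export
sum_to_proteins <- function(records, sfk_list = SFK_GENES) {
  if (nrow(records) == 0L)
    stop("no peptide records to sum")
  samples <- unique(records$sample)
  parts <- lapply(samples, function(s) {
    rec <- records[records$sample == s, , drop = FALSE]
    gene <- assign_ambiguous(rec)
    inh <- rec$regulatory == "inhibitory"
    entity <- ifelse(inh & gene %in% sfk_list, paste0(gene, "_i"), gene)
    value <- ifelse(inh, -rec$intensity, rec$intensity)
    data.frame(entity = entity, sample = s, value = value,
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, parts)
  sums <- tapply(long$value, list(long$entity, long$sample), sum)
  sums <- sums[, samples, drop = FALSE]  # keep input sample order
  phospho_matrix(sums, "protein")
}

#' Sum phosphopeptides into phosphorylation-site entities
#'
#' Peptides are summed by phosphorylation site irrespective of oxidized
#' methionine.  Peptides whose conserved sequence matches several proteins
#' either keep a compound id (e.g. `"FYN 531; SRC 530; YES1 537"`,
#' `inclusive = FALSE`) or are added to every candidate site entity
#' (`inclusive = TRUE`, so one peptide can contribute to several sites).
#' Inhibitory-site peptides contribute negative values.
#'
#' @param records peptide record data.frame.
#' @param inclusive logical; inclusive summation of shared peptides.
#' @return a site-level [phospho_matrix()].
#' @export
sum_to_sites <- function(records, inclusive = TRUE) {
  if (nrow(records) == 0L) stop("no peptide records to sum")
  value <- signed_intensity(records)
  if (inclusive) {
    site_lists <- split_field(records$sites)
    idx <- rep(seq_len(nrow(records)), lengths(site_lists))
    long <- data.frame(entity = unlist(site_lists),
                       sample = records$sample[idx],
                       value = value[idx], stringsAsFactors = FALSE)
  } else {
    long <- data.frame(entity = records$sites, sample = records$sample,
                       value = value, stringsAsFactors = FALSE)
  }
  samples <- unique(records$sample)
  sums <- tapply(long$value, list(long$entity, long$sample), sum)
  sums <- sums[, samples, drop = FALSE]
  phospho_matrix(sums, "site")
}

#' Average duplicate mass-spectrometry runs
#'
#' Duplicate runs of the same experiment are merged into one sample column
#' holding the mean of the two runs, ignoring missing values: `(10, NA)`
#' averages to `10`; only if both runs are missing does the merged cell stay
#' `NA`.  The merged column keeps the first run's sample id.
#'
#' @param m a [phospho_matrix()].
#' @param run_pairs list of length-2 character vectors of sample ids.
#' @export
merge_duplicate_runs <- function(m, run_pairs) {
  for (pair in run_pairs) {
    if (!all(pair %in% colnames(m)))
      stop("duplicate-run pair references absent sample(s): ",
           paste(setdiff(pair, colnames(m)), collapse = ", "))
    merged <- rowMeans(m[, pair, drop = FALSE], na.rm = TRUE)
    merged[is.nan(merged)] <- NA_real_
    m[, pair[1L]] <- merged
    m <- m[, setdiff(colnames(m), pair[2L]), drop = FALSE]
  }
  phospho_matrix(m, attr(m, "level"))
}
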