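#' Read or write a profile matrix as TSV
#'
#' The TSV dialect used throughout the package: the first column holds row
#' identifiers (genes or drugs), the header row holds cell-line identifiers,
#' and missing values are written as `NA`.
#'
#' @param m Numeric matrix with row and column names.
#' @param path File path.
#' @param id_col Name written for the identifier column (`"id"` on write;
#'   ignored on read, where the first column is always the identifier).
#' @return `read_matrix_tsv()` returns a numeric matrix with dimnames;
#'   `write_matrix_tsv()` returns `path` invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

# Write a data.frame as plain TSV (no quoting, NA as "NA").
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a correlation table
#'
#' Emits one row per drug-gene pair with the columns `drug_id`, `gene_id`,
#' `n_obs`, `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#' `holm_p` and `retained` (0/1 under the supplied policy).
#'
#' @param records Correlation records from [correlate_all()].
#' @param path Output TSV path.
#' @param policy A [filter_policy()] used to flag retained rows.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(records, path, policy = filter_policy()) {
  records$retained <- as.integer(retained_mask(records, policy))
  cols <- c("drug_id", "gene_id", "n_obs", "pearson_r", "pearson_p",
            "spearman_rho", "spearman_p", "holm_p", "retained")
  write_tsv(records[, cols], path)
}

#' Write or read a square similarity matrix as TSV
#'
#' @param S Symmetric numeric matrix with identical row/column names.
#' @param path File path.
#' @return The matrix (read) or `path` invisibly (write).
#' @export
write_similarity_tsv <- function(S, path) {
  write_matrix_tsv(S, path, id_col = "drug_id")
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  read_matrix_tsv(path)
}

#' Read or write a drug target-set map
#'
#' Long format: one `(drug_id, gene_id)` row per network edge.
#'
#' @param sets Named list mapping drug id to a character vector of gene ids.
#' @param path File path.
#' @return `read_target_sets()` returns a named list of character vectors.
#' @export
write_target_sets <- function(sets, path) {
  df <- data.frame(
    drug_id = rep(names(sets), lengths(sets)),
    gene_id = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_target_sets
#' @export
read_target_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(df$gene_id, factor(df$drug_id, levels = unique(df$drug_id)))
}
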