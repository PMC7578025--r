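#' Read a genes-by-samples expression matrix from TSV
#'
#' First column is the gene id, one column per sample.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix to TSV
#'
#' @param expr matrix with gene rownames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a model-keyed label table (subtypes or mutations) from TSV
#'
#' @param path TSV with a `model_id` column.
#' @return data.frame.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"model_id" %in% names(df))
    stop(path, ": expected a model_id column")
  df
}

#' Write a model-keyed label table to TSV
#'
#' @param df data.frame with a `model_id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an AUC matrix as TSV
#'
#' @param mat models x drugs matrix.
#' @param path TSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_auc_matrix <- function(mat, path) {
  df <- data.frame(model_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_auc_matrix
#' @export
read_auc_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
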