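# Plain-text I/O: gene x sample matrices as TSV (first column gene_id,
# header = sample ids in sample-sheet order), sample sheets as CSV.

#' Write / read a gene-by-sample matrix as TSV
#'
#' @param mat Numeric matrix with gene row names and sample column names.
#' @param path File path.
#' @return \code{read_matrix_tsv} returns the matrix; the writer returns the
#'   path invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write / read a sample sheet as CSV
#'
#' @param design Sample sheet data.frame.
#' @param path File path.
#' @export
write_sample_sheet <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# generic TSV writer for result tables
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
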