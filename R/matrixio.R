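#' Write a labelled matrix as TSV
#'
#' Full-precision TSV with a header row of column labels and a leading label
#' column; the canonical on-disk form of correlation maps and block summaries.
#'
#' @param matrix numeric matrix
#' @param row_labels character/numeric vector, length `nrow(matrix)`
#' @param col_labels character/numeric vector, length `ncol(matrix)`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_matrix_tsv <- function(matrix, row_labels, col_labels, path) {
  matrix <- as.matrix(matrix)
  if (length(row_labels) != nrow(matrix))
    stop("row_labels length ", length(row_labels),
         " does not match nrow ", nrow(matrix))
  if (length(col_labels) != ncol(matrix))
    stop("col_labels length ", length(col_labels),
         " does not match ncol ", ncol(matrix))
  df <- data.frame(label = as.character(row_labels),
                   format(matrix, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("label", as.character(col_labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path
#' @return numeric matrix with `dimnames` from the label row/column
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}
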