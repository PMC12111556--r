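#' Construct a tagged expression matrix
#'
#' A thin wrapper around a numeric gene-by-sample matrix that carries a
#' platform tag so downstream filters can check they are being fed the kind
#' of data they expect: `"bulk_log"` for log2-scale microarray-like
#' intensities, `"fpkm"` for non-negative single-cell FPKM-like values.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param platform `"bulk_log"` or `"fpkm"`.
#' @return the matrix with a `platform` attribute and class `expr_matrix`.
#' @export
expression_matrix <- function(values, platform = c("bulk_log", "fpkm")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("expression_matrix: 'values' must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop_input("expression_matrix: rownames must be unique gene ids")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop_input("expression_matrix: colnames must be unique sample ids")
  if (any(!is.finite(values)))
    stop_input("expression_matrix: all values must be finite")
  if (platform == "fpkm" && any(values < 0))
    stop_input("expression_matrix: fpkm values must be >= 0")
  structure(values, platform = platform,
            class = c("expr_matrix", class(matrix())))
}

#' Platform tag of an expression matrix
#' @param x an `expr_matrix` (or plain matrix, returning `NULL`).
#' @return the platform string or `NULL`.
#' @export
platform_of <- function(x) attr(x, "platform", exact = TRUE)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, platform=%s\n",
              nrow(x), ncol(x), platform_of(x)))
  invisible(x)
}

# row subset that keeps the platform tag
subset_expr <- function(x, genes) {
  out <- x[genes, , drop = FALSE]
  attr(out, "platform") <- platform_of(x)
  class(out) <- class(x)
  out
}

# unbiased per-gene (row) variance without apply() overhead
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) stop_input("variance undefined for a single-sample matrix")
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Write / read an expression matrix as TSV
#'
#' Genes in rows; first column `gene_id`, remaining columns one per sample.
#' UTF-8, tab-delimited, '.' decimal.
#'
#' @param x an `expr_matrix`.
#' @param path output file.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param platform platform tag to attach on read.
#' @export
read_expression_tsv <- function(path, platform = c("bulk_log", "fpkm")) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, match.arg(platform))
}

#' Write / read a gene set as one-id-per-line text
#' @param genes character vector of gene ids.
#' @param path file path.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) readLines(path)
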