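#' Construct a single-nucleus expression matrix
#'
#' Holds non-negative normalized expression values, one row per nucleus
#' (barcode) and one column per gene. All readers normalize orientation so
#' that nuclei are rows.
#'
#' @param values numeric matrix, nuclei x genes, all entries >= 0.
#' @param barcodes unique nucleus identifiers; default taken from rownames.
#' @param genes unique gene identifiers; default taken from colnames.
#' @param binary logical; TRUE when `values` has been binarized.
#' @return an object of class `expression_matrix` with fields `barcodes`,
#'   `genes`, `values`, `binary_flag`.
#' @export
expression_matrix <- function(values, barcodes = rownames(values),
                              genes = colnames(values), binary = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L) stop("validation error: no nuclei")
  if (ncol(values) == 0L) stop("validation error: no genes")
  if (is.null(barcodes)) barcodes <- paste0("nucleus", seq_len(nrow(values)))
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(barcodes), as.character(genes))
  obj <- structure(
    list(barcodes = as.character(barcodes), genes = as.character(genes),
         values = values, binary_flag = isTRUE(binary)),
    class = "expression_matrix"
  )
  validate_expression_matrix(obj)
}

#' Validate an expression matrix's invariants
#' @param expr an `expression_matrix`.
#' @return the object invisibly, or an error.
#' @export
validate_expression_matrix <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (nrow(expr$values) == 0L) stop("validation error: no nuclei")
  if (ncol(expr$values) == 0L) stop("validation error: no genes")
  if (anyDuplicated(expr$barcodes))
    stop("validation error: duplicate barcodes")
  if (anyDuplicated(expr$genes))
    stop("validation error: duplicate gene identifiers")
  if (nrow(expr$values) != length(expr$barcodes) ||
      ncol(expr$values) != length(expr$genes))
    stop("validation error: values shape does not match barcodes/genes")
  if (any(expr$values < 0))
    stop("validation error: negative expression values")
  if (expr$binary_flag && !all(expr$values %in% c(0, 1)))
    stop("validation error: binary_flag set but values are not 0/1")
  expr
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", length(x$barcodes), " nuclei, ",
      length(x$genes), " genes", if (x$binary_flag) " (binarized)", "\n",
      sep = "")
  invisible(x)
}

#' Subset an expression matrix
#' @param expr an `expression_matrix`.
#' @param nuclei logical/integer/character index of nuclei to keep.
#' @param genes logical/integer/character index of genes to keep.
#' @return an `expression_matrix` with row order preserved.
#' @export
subset_expression <- function(expr, nuclei = NULL, genes = NULL) {
  if (is.null(nuclei)) nuclei <- seq_along(expr$barcodes)
  if (is.character(nuclei)) nuclei <- match(nuclei, expr$barcodes)
  if (is.null(genes)) genes <- seq_along(expr$genes)
  if (is.character(genes)) genes <- match(genes, expr$genes)
  expression_matrix(expr$values[nuclei, genes, drop = FALSE],
                    barcodes = expr$barcodes[nuclei],
                    genes = expr$genes[genes],
                    binary = expr$binary_flag)
}

#' Read an expression matrix from disk
#'
#' Accepts either a dense delimited table or a Matrix Market sparse triplet
#' plus gene and barcode lists (one identifier per line, first column used).
#' Matrix Market input follows the 10x convention of genes x barcodes and is
#' transposed internally; dense input orientation is declared by
#' `orientation`.
#'
#' @param path_matrix path to the dense table or `.mtx` file.
#' @param path_genes,path_barcodes identifier lists for Matrix Market input.
#' @param orientation of the dense table: `"nuclei_by_genes"` (rows are
#'   nuclei) or `"genes_by_nuclei"`.
#' @param sep field separator for dense input; inferred from extension by
#'   default.
#' @return an `expression_matrix` (dense storage).
#' @export
read_expression <- function(path_matrix, path_genes = NULL,
                            path_barcodes = NULL,
                            orientation = c("nuclei_by_genes", "genes_by_nuclei"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path_matrix)) stop("file not found: ", path_matrix)
  if (grepl("\\.mtx$", path_matrix)) {
    if (is.null(path_genes) || is.null(path_barcodes))
      stop("format error: Matrix Market input requires gene and barcode lists")
    m <- as.matrix(Matrix::readMM(path_matrix))
    genes <- utils::read.table(path_genes, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    barcodes <- utils::read.table(path_barcodes, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes))
      stop("format error: matrix has ", nrow(m), " rows but gene list has ",
           length(genes), " entries")
    if (ncol(m) != length(barcodes))
      stop("format error: matrix has ", ncol(m), " columns but barcode list has ",
           length(barcodes), " entries")
    values <- t(m)
    dimnames(values) <- list(barcodes, genes)
  } else {
    if (is.null(sep))
      sep <- if (grepl("\\.tsv$|\\.txt$", path_matrix)) "\t" else ","
    df <- utils::read.table(path_matrix, header = TRUE, sep = sep,
                            row.names = 1, check.names = FALSE)
    values <- as.matrix(df)
    if (orientation == "genes_by_nuclei") values <- t(values)
  }
  if (nrow(values) == 0L) stop("validation error: no nuclei")
  expression_matrix(values)
}

#' Write an expression matrix as Matrix Market triplet plus id lists
#'
#' Writes `matrix.mtx` (genes x barcodes, 10x convention), `genes.tsv` and
#' `barcodes.tsv` into `out_dir`.
#'
#' @param expr an `expression_matrix`.
#' @param out_dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_expression_mtx <- function(expr, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(expr$values), sparse = TRUE),
                  file.path(out_dir, "matrix.mtx"))
  writeLines(expr$genes, file.path(out_dir, "genes.tsv"))
  writeLines(expr$barcodes, file.path(out_dir, "barcodes.tsv"))
  invisible(out_dir)
}

#' Binarize expression values
#'
#' A gene is called expressed in a nucleus when its normalized expression is
#' greater than zero, non-expressed when it is exactly zero.
#'
#' @param expr an `expression_matrix` with values >= 0.
#' @return an `expression_matrix` of 0/1 values with `binary_flag` set.
#' @export
binarize <- function(expr) {
  validate_expression_matrix(expr)
  expression_matrix((expr$values > 0) + 0, barcodes = expr$barcodes,
                    genes = expr$genes, binary = TRUE)
}

#' Simple log-normalization for synthetic data
#'
#' Applies `log2(1 + x)` elementwise. This is the only normalization provided
#' by the package; real datasets are expected to arrive already normalized
#' upstream.
#'
#' @param expr an `expression_matrix`.
#' @return an `expression_matrix` on the log scale.
#' @export
log_normalize <- function(expr) {
  expression_matrix(log2(1 + expr$values), barcodes = expr$barcodes,
                    genes = expr$genes)
}
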