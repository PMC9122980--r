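#' Construct a spatial reference map
#'
#' A spatial map is the 3D reconstruction of an organ: one row per cell with
#' its (x, y, z) position and a binary call (0/1) for each of a small set of
#' reference genes whose spatial expression pattern is known.
#'
#' @param cell_ids character vector of unique cell identifiers.
#' @param coords numeric matrix (cells x 3) of positions; columns x, y, z.
#'   Coordinates are treated as unitless Euclidean (typically micrometres).
#' @param ref_genes character vector of reference-gene identifiers, one per
#'   column of `ref_expr`.
#' @param ref_expr cells x reference-genes matrix with entries in \{0, 1\}.
#' @param attrs optional data.frame of per-cell scalars (e.g. volume,
#'   lineage, growth), one row per cell.
#'
#' @return An object of class `spatial_map` with fields `cell_ids`, `coords`,
#'   `ref_genes`, `ref_expr`, `attrs`.
#' @export
spatial_map <- function(cell_ids, coords, ref_genes, ref_expr, attrs = NULL) {
  cell_ids <- as.character(cell_ids)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  ref_expr <- as.matrix(ref_expr)
  storage.mode(ref_expr) <- "double"
  ref_genes <- as.character(ref_genes)
  colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  rownames(coords) <- cell_ids
  dimnames(ref_expr) <- list(cell_ids, ref_genes)
  obj <- structure(
    list(cell_ids = cell_ids, coords = coords, ref_genes = ref_genes,
         ref_expr = ref_expr, attrs = attrs),
    class = "spatial_map"
  )
  validate_spatial_map(obj)
}

#' Validate a spatial map's invariants
#'
#' Checks that cell ids are unique, coordinates are finite and 3D, the
#' reference matrix is strictly binary and its shape matches `ref_genes`.
#'
#' @param map a `spatial_map`.
#' @return the map, invisibly unchanged, or an error.
#' @export
validate_spatial_map <- function(map) {
  stopifnot(inherits(map, "spatial_map"))
  if (anyDuplicated(map$cell_ids))
    stop("validation error: duplicate cell ids in spatial map: ",
         paste(unique(map$cell_ids[duplicated(map$cell_ids)]), collapse = ", "))
  if (nrow(map$coords) != length(map$cell_ids))
    stop("validation error: coords rows do not match cell ids")
  if (ncol(map$coords) != 3L)
    stop("format error: spatial map requires x, y, z coordinate columns")
  if (!all(is.finite(map$coords)))
    stop("validation error: non-finite coordinates in spatial map")
  if (ncol(map$ref_expr) != length(map$ref_genes))
    stop("validation error: ref_expr columns do not match ref_genes")
  if (nrow(map$ref_expr) != length(map$cell_ids))
    stop("validation error: ref_expr rows do not match cell ids")
  if (!all(map$ref_expr %in% c(0, 1)))
    stop("validation error: spatial map reference calls must be 0/1 ",
         "(use binarize_threshold= when reading to coerce)")
  map
}

#' Number of cells / reference genes in a spatial map
#' @param map a `spatial_map`.
#' @return integer count.
#' @export
n_cells <- function(map) length(map$cell_ids)

#' @rdname n_cells
#' @export
n_ref_genes <- function(map) length(map$ref_genes)

#' @export
print.spatial_map <- function(x, ...) {
  cat("spatial_map: ", n_cells(x), " cells, ", n_ref_genes(x),
      " reference genes\n", sep = "")
  cat("  coords range: x [", paste(signif(range(x$coords[, 1]), 4), collapse = ", "),
      "], z [", paste(signif(range(x$coords[, 3]), 4), collapse = ", "), "]\n", sep = "")
  if (!is.null(x$attrs))
    cat("  attrs:", paste(names(x$attrs), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a spatial map by cells and/or reference genes
#'
#' @param map a `spatial_map`.
#' @param cells logical/integer/character index of cells to keep.
#' @param genes logical/integer/character index of reference genes to keep.
#' @return a `spatial_map` with row order preserved.
#' @export
subset_spatial_map <- function(map, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_along(map$cell_ids)
  if (is.character(cells)) cells <- match(cells, map$cell_ids)
  if (is.null(genes)) genes <- seq_along(map$ref_genes)
  if (is.character(genes)) genes <- match(genes, map$ref_genes)
  spatial_map(
    cell_ids = map$cell_ids[cells],
    coords = map$coords[cells, , drop = FALSE],
    ref_genes = map$ref_genes[genes],
    ref_expr = map$ref_expr[cells, genes, drop = FALSE],
    attrs = if (!is.null(map$attrs)) map$attrs[cells, , drop = FALSE]
  )
}

# Columns recognized as per-cell attributes rather than reference genes when
# reading the canonical CSV schema (cell_id,x,y,z,<gene>...).
.attr_columns <- c("volume", "lineage", "growth")

#' Read a spatial reference map from CSV/TSV
#'
#' The canonical on-disk schema is a delimited table with header
#' `cell_id,x,y,z,<gene>...`; optional columns named `volume`, `lineage` or
#' `growth` are stored as per-cell attributes. Gene columns must be strictly
#' 0/1 unless `binarize_threshold` is given, in which case values >=
#' threshold become 1 and values below become 0.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`; default inferred from the extension.
#' @param binarize_threshold optional numeric; coerce non-binary gene columns.
#' @return a `spatial_map`, with file row order preserved.
#' @export
read_spatial_map <- function(path, format = NULL, binarize_threshold = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.tsv$|\\.txt$", path)) "tsv" else "csv"
  format <- match.arg(format, c("csv", "tsv"))
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("format error: spatial map file must have columns ",
         paste(need, collapse = ", "))
  attr_cols <- intersect(.attr_columns, names(df))
  gene_cols <- setdiff(names(df), c(need, attr_cols))
  if (length(gene_cols) < 1L)
    stop("format error: spatial map file has no reference-gene columns")
  expr <- as.matrix(df[, gene_cols, drop = FALSE])
  storage.mode(expr) <- "double"
  if (!is.null(binarize_threshold)) {
    expr <- (expr >= binarize_threshold) + 0
  }
  message("read_spatial_map: ", nrow(df), " cells, ",
          length(gene_cols), " reference genes")
  spatial_map(
    cell_ids = df$cell_id,
    coords = as.matrix(df[, c("x", "y", "z")]),
    ref_genes = gene_cols,
    ref_expr = expr,
    attrs = if (length(attr_cols)) df[, attr_cols, drop = FALSE]
  )
}

#' Write a spatial map to the canonical CSV schema
#'
#' Inverse of [read_spatial_map()]; round trips preserve all identifiers and
#' values exactly.
#'
#' @param map a `spatial_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spatial_map <- function(map, path) {
  df <- data.frame(cell_id = map$cell_ids,
                   x = map$coords[, 1], y = map$coords[, 2], z = map$coords[, 3],
                   check.names = FALSE)
  if (!is.null(map$attrs)) df <- cbind(df, map$attrs)
  df <- cbind(df, as.data.frame(map$ref_expr, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
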