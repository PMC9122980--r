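#' Standardize a matrix gene-wise to mean 0, variance 1
#'
#' Uses the population variance (divisor n). Genes with zero variance map to
#' all-zeros rather than dividing by zero.
#'
#' @param values cells x genes numeric matrix.
#' @return matrix of the same shape.
#' @export
standardize_genes <- function(values) {
  values <- as.matrix(values)
  mu <- colMeans(values)
  centred <- sweep(values, 2, mu)
  sdp <- sqrt(colMeans(centred^2))
  out <- sweep(centred, 2, ifelse(sdp > 0, sdp, 1), "/")
  out[, sdp == 0] <- 0
  out
}

#' Write a reconstructed atlas to disk
#'
#' Writes (i) `predicted_expression.csv`, a cells x genes table keyed by
#' cell id; (ii) `atlas_long.csv`, a long-format table
#' (`cell_id,x,y,z,gene,value`) suitable for 3D viewers; and optionally
#' (iii) `predicted_expression_standardized.csv`, a per-gene standardized
#' copy (mean 0, variance 1; zero-variance genes become zeros), the scaling
#' used for figure-style visual comparison.
#'
#' @param atlas a `reconstructed_atlas`.
#' @param map the `spatial_map` the atlas was computed on; cell order must
#'   match.
#' @param out_dir output directory, created if needed.
#' @param standardized also write the standardized copy?
#' @return character vector of file paths written, invisibly.
#' @export
write_atlas <- function(atlas, map, out_dir, standardized = TRUE) {
  stopifnot(inherits(atlas, "reconstructed_atlas"),
            inherits(map, "spatial_map"))
  if (!identical(atlas$cell_ids, map$cell_ids))
    stop("validation error: atlas cell order does not match spatial map")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  wide <- data.frame(cell_id = atlas$cell_ids,
                     as.data.frame(atlas$values, check.names = FALSE),
                     check.names = FALSE)
  p <- file.path(out_dir, "predicted_expression.csv")
  utils::write.csv(wide, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  long <- data.frame(
    cell_id = rep(atlas$cell_ids, times = length(atlas$genes)),
    x = rep(map$coords[, 1], times = length(atlas$genes)),
    y = rep(map$coords[, 2], times = length(atlas$genes)),
    z = rep(map$coords[, 3], times = length(atlas$genes)),
    gene = rep(atlas$genes, each = length(atlas$cell_ids)),
    value = as.vector(atlas$values))
  p <- file.path(out_dir, "atlas_long.csv")
  utils::write.csv(long, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  if (standardized) {
    std <- data.frame(cell_id = atlas$cell_ids,
                      as.data.frame(standardize_genes(atlas$values),
                                    check.names = FALSE),
                      check.names = FALSE)
    p <- file.path(out_dir, "predicted_expression_standardized.csv")
    utils::write.csv(std, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a predicted-expression CSV back into a reconstructed atlas
#' @param path a `predicted_expression.csv` written by [write_atlas()].
#' @return a `reconstructed_atlas` (without provenance).
#' @export
read_atlas <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$cell_id
  reconstructed_atlas(values, cell_ids = df$cell_id)
}

#' Read a one-column gene list
#' @param path file with one gene identifier per line (first column used).
#' @return character vector.
#' @export
read_gene_set <- function(path) {
  utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)[[1]]
}

#' Read per-nucleus cluster labels
#'
#' Two-column delimited file `barcode,cluster` (header optional, detected
#' when the second field of the first line is non-numeric and named
#' "cluster").
#'
#' @param path file path.
#' @return named vector of cluster ids keyed by barcode.
#' @export
read_cluster_labels <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  first <- strsplit(readLines(path, n = 1), sep)[[1]]
  header <- identical(tolower(first[2]), "cluster")
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  labels <- df[[2]]
  names(labels) <- as.character(df[[1]])
  if (anyDuplicated(names(labels)))
    stop("validation error: barcode labelled more than once")
  labels
}

#' Export a transport plan as Matrix Market plus row/column id lists
#'
#' @param plan a `transport_plan`.
#' @param out_dir output directory.
#' @return the directory, invisibly.
#' @export
write_plan <- function(plan, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(plan$T, sparse = TRUE),
                  file.path(out_dir, "plan.mtx"))
  writeLines(rownames(plan$T), file.path(out_dir, "plan_rows.tsv"))
  writeLines(colnames(plan$T), file.path(out_dir, "plan_cols.tsv"))
  invisible(out_dir)
}

#' Write a JSON run manifest
#'
#' Records parameters, seeds, filter reports and input checksums for a run so
#' that results can be traced back to their inputs.
#'
#' @param manifest a named list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(manifest, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Checksum helper for run manifests
#' @param path file path.
#' @return md5 string, or NA if the file does not exist.
#' @keywords internal
file_checksum <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  as.character(tools::md5sum(path))
}
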