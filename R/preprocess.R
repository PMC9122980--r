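#' @title Filtering of the spatial map and the snRNA-seq matrix
#' @description
#' Before integration, the spatial map and the single-nucleus matrix are
#' pruned so that only informative cells, nuclei and reference genes remain:
#' map cells expressing no reference gene, reference genes that are constant
#' or absent from the snRNA-seq data, map cells with too few expressed
#' reference genes or with a rare binary combination, low-prevalence
#' snRNA-seq genes, and nuclei expressing none of the final reference genes.
#' Each filter returns its result together with a `filter_report` recording
#' what was removed.
#' @name preprocess
NULL

filter_report <- function(stage, item_ids, parameters = list()) {
  structure(list(stage = stage, items_removed = length(item_ids),
                 item_ids = item_ids, parameters = parameters),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report [", x$stage, "]: ", x$items_removed, " removed\n",
      sep = "")
  invisible(x)
}

#' Remove spatial-map cells expressing no reference gene
#'
#' @param map a `spatial_map`.
#' @return list with elements `map` (survivors, order preserved) and
#'   `report` (a `filter_report`).
#' @export
filter_cells_no_reference <- function(map) {
  validate_spatial_map(map)
  drop <- rowSums(map$ref_expr) == 0
  if (all(drop)) stop("empty spatial map: all cells removed")
  list(map = subset_spatial_map(map, cells = !drop),
       report = filter_report("cells_no_reference", map$cell_ids[drop]))
}

#' Remove uninformative reference genes
#'
#' Drops reference-gene columns that are constant across the spatial map's
#' cells, or whose identifier is absent from the snRNA-seq gene list. With
#' `scope = "nuclei"` the constantness test is instead evaluated on the
#' binarized snRNA-seq data (see the methods vignette for why both readings
#' are offered).
#'
#' @param map a `spatial_map`.
#' @param expr an `expression_matrix`.
#' @param scope where constantness is evaluated: `"map"` (default) or
#'   `"nuclei"`.
#' @return list with elements `map` and `report`.
#' @export
filter_uninformative_reference_genes <- function(map, expr,
                                                 scope = c("map", "nuclei")) {
  scope <- match.arg(scope)
  validate_spatial_map(map)
  validate_expression_matrix(expr)
  absent <- !(map$ref_genes %in% expr$genes)
  if (scope == "map") {
    constant <- apply(map$ref_expr, 2, function(v) length(unique(v)) == 1L)
  } else {
    constant <- vapply(map$ref_genes, function(g) {
      if (!(g %in% expr$genes)) return(FALSE)
      v <- expr$values[, g] > 0
      length(unique(v)) == 1L
    }, logical(1))
  }
  drop <- absent | constant
  if (all(drop)) stop("empty spatial map: all reference genes removed")
  list(map = subset_spatial_map(map, genes = !drop),
       report = filter_report("uninformative_reference_genes",
                              map$ref_genes[drop],
                              list(scope = scope)))
}

#' Remove map cells with few expressed genes or rare combinations
#'
#' A cell is removed when it expresses fewer than `min_genes` reference
#' genes, or when its exact binary reference pattern is shared by fewer than
#' `min_combo_support` *other* cells. Both conditions are evaluated on the
#' state of the map as passed in (no cascading within the step).
#'
#' @param map a `spatial_map` (after the previous two filters).
#' @param min_genes minimum expressed reference genes per cell.
#' @param min_combo_support minimum number of other cells sharing the exact
#'   pattern.
#' @return list with elements `map` and `report`.
#' @export
filter_sparse_and_rare_combination_cells <- function(map, min_genes = 3,
                                                     min_combo_support = 4) {
  validate_spatial_map(map)
  few <- rowSums(map$ref_expr) < min_genes
  pattern <- apply(map$ref_expr, 1, paste, collapse = "")
  support <- table(pattern)
  rare <- (as.vector(support[pattern]) - 1L) < min_combo_support
  drop <- few | rare
  if (all(drop)) stop("empty spatial map: all cells removed")
  list(map = subset_spatial_map(map, cells = !drop),
       report = filter_report("sparse_and_rare_combination_cells",
                              map$cell_ids[drop],
                              list(min_genes = min_genes,
                                   min_combo_support = min_combo_support)))
}

#' Remove low-prevalence genes from the snRNA-seq matrix
#'
#' Genes with nonzero expression in fewer than `min_cells` nuclei are
#' removed, except those in `always_keep` (genes retained for their
#' biological importance regardless of prevalence).
#'
#' @param expr an `expression_matrix`.
#' @param min_cells prevalence threshold (strictly fewer than this removes).
#' @param always_keep character vector of protected gene identifiers.
#' @return list with elements `expr` and `report`.
#' @export
filter_low_prevalence_genes <- function(expr, min_cells = 30,
                                        always_keep = character(0)) {
  validate_expression_matrix(expr)
  prevalence <- colSums(expr$values > 0)
  drop <- prevalence < min_cells & !(expr$genes %in% always_keep)
  list(expr = if (any(drop)) subset_expression(expr, genes = !drop) else expr,
       report = filter_report("low_prevalence_genes", expr$genes[drop],
                              list(min_cells = min_cells,
                                   always_keep = always_keep)))
}

#' Remove nuclei expressing none of the map's reference genes
#'
#' @param expr an `expression_matrix`.
#' @param map a `spatial_map` already filtered to its final reference genes.
#' @return list with elements `expr` and `report`.
#' @export
filter_nuclei_no_reference <- function(expr, map) {
  validate_expression_matrix(expr)
  refs <- intersect(map$ref_genes, expr$genes)
  if (length(refs) == 0L)
    stop("no reference genes present in the expression matrix")
  drop <- rowSums(expr$values[, refs, drop = FALSE] > 0) == 0
  if (all(drop)) stop("empty result: all nuclei removed")
  list(expr = if (any(drop)) subset_expression(expr, nuclei = !drop) else expr,
       report = filter_report("nuclei_no_reference", expr$barcodes[drop]))
}

#' Select genes most correlated with the reference genes
#'
#' For each reference gene, all snRNA-seq genes are ranked by Pearson
#' correlation (across nuclei) with that reference gene's expression, and the
#' union of the per-reference top-`top_n` lists is returned. These genes
#' replace the generic highly-variable-gene set when building the
#' nucleus-nucleus distance graph, anchoring the graph to genes with known
#' spatial relevance.
#'
#' Undefined correlations (constant genes) are treated as 0; ties at the
#' rank-`top_n` boundary are broken by gene identifier so the selection is
#' deterministic.
#'
#' @param expr a filtered `expression_matrix`.
#' @param map the final `spatial_map` (its `ref_genes` must all be in
#'   `expr`).
#' @param top_n genes taken per reference gene.
#' @return character vector of selected gene identifiers (union, in `expr`
#'   gene order).
#' @export
select_reference_correlated_genes <- function(expr, map, top_n = 100) {
  validate_expression_matrix(expr)
  missing <- setdiff(map$ref_genes, expr$genes)
  if (length(missing))
    stop("reference gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  X <- expr$values
  # constant genes have no defined correlation with anything; never selected
  defined <- (colMeans(X^2) - colMeans(X)^2) > 0
  X <- X[, defined, drop = FALSE]
  R <- expr$values[, map$ref_genes, drop = FALSE]
  cors <- suppressWarnings(stats::cor(X, R))
  cors[is.na(cors)] <- 0
  selected <- unique(unlist(lapply(seq_len(ncol(cors)), function(j) {
    ord <- order(-cors[, j], rownames(cors))
    rownames(cors)[ord[seq_len(min(top_n, nrow(cors)))]]
  })))
  expr$genes[expr$genes %in% selected]
}
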