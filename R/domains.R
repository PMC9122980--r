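#' Select genes for expression-domain identification
#'
#' High-variable, well-predicted genes drive the domain clustering: a gene
#' is selected when its PEP score exceeds `pep_min` and the variance of its
#' predicted expression across cells exceeds `var_min` (both strict).
#' Variance is evaluated on the untransformed atlas; the defaults
#' (`pep_min = 0.13`, `var_min = 3`) are the values used for the floral
#' meristem and are scale-dependent — adjust `var_min` to the dynamic range
#' of the expression values at hand.
#'
#' @param atlas a `reconstructed_atlas`.
#' @param pep a `pep_table` sharing genes with the atlas.
#' @param pep_min,var_min strict lower thresholds.
#' @return character vector of selected genes.
#' @export
select_domain_genes <- function(atlas, pep, pep_min = 0.13, var_min = 3) {
  pep_map <- stats::setNames(pep$pep, pep$gene)
  shared <- intersect(atlas$genes, pep$gene)
  v <- apply(atlas$values[, shared, drop = FALSE], 2, stats::var)
  sel <- shared[!is.na(pep_map[shared]) & pep_map[shared] > pep_min &
                  v > var_min]
  if (length(sel) == 0L)
    stop("no genes pass pep_min = ", pep_min, " and var_min = ", var_min,
         "; consider lowering the thresholds")
  sel
}

#' Log-transform and standardize atlas genes
#'
#' Per gene: `y = log2(x + 1)`, then `(y - mean) / sd` with the population
#' standard deviation. Zero-variance genes map to all-zeros.
#'
#' @param atlas a `reconstructed_atlas` (values >= 0).
#' @param genes genes to transform; default all.
#' @return cells x genes matrix of standardized values.
#' @export
standardize_log <- function(atlas, genes = NULL) {
  if (is.null(genes)) genes <- atlas$genes
  standardize_genes(log2(atlas$values[, genes, drop = FALSE] + 1))
}

#' Identify expression domains by hierarchical clustering
#'
#' Cells are clustered on the Euclidean distance between their standardized
#' expression profiles using agglomerative hierarchical clustering with
#' average linkage, and the tree is cut into exactly `k` clusters. Labels
#' are renumbered by decreasing cluster size so the output is deterministic
#' and invariant to cell order.
#'
#' @param standardized cells x genes matrix from [standardize_log()].
#' @param k number of expression domains (15 for the floral meristem).
#' @param linkage agglomeration method (only `"average"` supported).
#' @param metric distance between profiles (only `"euclidean"` supported).
#' @return an object of class `domain_assignment`: list with `labels`
#'   (named integer vector, cell -> domain in 1..k), `k`, `linkage`,
#'   `genes`.
#' @export
cluster_domains <- function(standardized, k = 15, linkage = "average",
                            metric = "euclidean") {
  linkage <- match.arg(linkage, "average")
  metric <- match.arg(metric, "euclidean")
  standardized <- as.matrix(standardized)
  n <- nrow(standardized)
  if (k > n) stop("k exceeds the number of cells")
  if (k == n) {
    labels <- seq_len(n)
  } else {
    hc <- stats::hclust(stats::dist(standardized, method = metric),
                        method = linkage)
    raw <- stats::cutree(hc, k = k)
    sizes <- table(raw)
    relabel <- stats::setNames(seq_along(sizes),
                               names(sort(sizes, decreasing = TRUE)))
    labels <- as.integer(relabel[as.character(raw)])
  }
  names(labels) <- rownames(standardized)
  structure(list(labels = labels, k = as.integer(k), linkage = linkage,
                 genes = colnames(standardized)),
            class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat("domain_assignment: ", length(x$labels), " cells in ",
      length(unique(x$labels)), " domains (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Per-domain mean expression
#'
#' @param atlas a `reconstructed_atlas` (untransformed values).
#' @param assignment a `domain_assignment` covering the atlas cells.
#' @return an object of class `domain_expression_table`: list with `means`
#'   (domain x gene matrix) and `counts` (cells per domain).
#' @export
domain_means <- function(atlas, assignment) {
  labels <- assignment$labels[atlas$cell_ids]
  if (any(is.na(labels)))
    stop("assignment does not cover all atlas cells")
  doms <- sort(unique(assignment$labels))
  means <- do.call(rbind, lapply(doms, function(d) {
    idx <- which(labels == d)
    if (length(idx) == 0L) {
      warning("domain ", d, " is empty; means are NA")
      return(rep(NA_real_, length(atlas$genes)))
    }
    colMeans(atlas$values[idx, , drop = FALSE])
  }))
  dimnames(means) <- list(paste0("domain", doms), atlas$genes)
  counts <- stats::setNames(as.integer(table(factor(labels, levels = doms))),
                            paste0("domain", doms))
  structure(list(means = means, counts = counts),
            class = "domain_expression_table")
}

#' Mean expression over a reference-gene-positive domain
#'
#' Selects the spatial cells where the named reference gene(s) have a
#' binary call of 1 (all of them, for combinations such as an AP3/AG whorl
#' overlap) and returns the per-gene mean predicted expression over that
#' cell set.
#'
#' @param atlas a `reconstructed_atlas` aligned with `map`.
#' @param map the `spatial_map`.
#' @param ref_genes one or more reference genes defining the domain.
#' @return named numeric vector of per-gene means.
#' @export
homeotic_domain_expression <- function(atlas, map, ref_genes) {
  stopifnot(identical(atlas$cell_ids, map$cell_ids))
  missing <- setdiff(ref_genes, map$ref_genes)
  if (length(missing))
    stop("not reference genes: ", paste(missing, collapse = ", "))
  inside <- rowSums(map$ref_expr[, ref_genes, drop = FALSE] == 1) ==
    length(ref_genes)
  if (!any(inside)) stop("empty domain: no cell positive for ",
                         paste(ref_genes, collapse = " & "))
  colMeans(atlas$values[inside, , drop = FALSE])
}

#' Log2 fold-change between two domain mean vectors
#'
#' `log2((a + pc) / (b + pc))` per gene, with pseudocount `pc` (default 1)
#' since predicted means can be exactly zero.
#'
#' @param a,b named mean vectors on shared genes.
#' @param pc pseudocount.
#' @return named numeric vector of log2 fold-changes over shared genes.
#' @export
domain_log2fc <- function(a, b, pc = 1) {
  shared <- intersect(names(a), names(b))
  log2((a[shared] + pc) / (b[shared] + pc))
}

#' Temporally regulated genes per expression domain
#'
#' Given per-domain mean tables from two time points mapped onto the same
#' spatial reference (identical domain labels), reports the genes whose
#' per-domain log2 fold-change `log2((meanA + 1)/(meanB + 1))` exceeds
#' `lfc_min` (up) or falls below `-lfc_min` (down); both strict.
#'
#' @param tableA,tableB `domain_expression_table`s with identical domain
#'   labels and gene sets (A is the later time point).
#' @param lfc_min fold-change threshold on the log2 scale.
#' @return named list per domain, each with `up` and `down` gene vectors.
#' @export
temporal_fold_change <- function(tableA, tableB, lfc_min = 1) {
  if (!identical(rownames(tableA$means), rownames(tableB$means)))
    stop("domain label mismatch between the two tables")
  if (!identical(colnames(tableA$means), colnames(tableB$means)))
    stop("gene set mismatch between the two tables")
  out <- lapply(rownames(tableA$means), function(d) {
    lfc <- log2((tableA$means[d, ] + 1) / (tableB$means[d, ] + 1))
    list(up = colnames(tableA$means)[!is.na(lfc) & lfc > lfc_min],
         down = colnames(tableA$means)[!is.na(lfc) & lfc < -lfc_min])
  })
  stats::setNames(out, rownames(tableA$means))
}

#' Relative expression of a gene list against a background
#'
#' Per sample: median expression over `gene_list` minus median over
#' `background` (the set of genes whose spatial expression is predicted).
#' Medians use the standard midpoint-of-middle-two convention for even
#' sizes.
#'
#' @param gene_list character vector (e.g. a domain's upregulated genes).
#' @param external_expr genes x samples matrix of external expression.
#' @param background character vector of background genes.
#' @return named numeric vector, one relative median per sample.
#' @export
signature_relative_expression <- function(gene_list, external_expr,
                                          background) {
  external_expr <- as.matrix(external_expr)
  gl <- intersect(gene_list, rownames(external_expr))
  bg <- intersect(background, rownames(external_expr))
  if (length(gl) == 0L || length(bg) == 0L)
    stop("empty intersection with the external expression table")
  apply(external_expr, 2, function(col) {
    stats::median(col[gl]) - stats::median(col[bg])
  })
}

#' Center a gene x group matrix by row means
#'
#' Relative expression: each gene's mean across groups/samples is
#' subtracted, so values express deviation from the gene's own average.
#'
#' @param values gene x group numeric matrix with >= 2 columns.
#' @return centered matrix of the same shape (row means 0).
#' @export
relative_expression <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 groups")
  sweep(values, 1, rowMeans(values))
}
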