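#' Area under the ROC curve
#'
#' Computed in its Mann-Whitney form: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, with ties counting 1/2.
#' Average ranks make this exact in the presence of tied scores.
#'
#' @param scores numeric vector of predicted values.
#' @param labels binary vector (0/1 or logical) of the same length, with at
#'   least one positive and one negative.
#' @return a number in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("auroc undefined: labels contain a single class")
  r <- rank(scores)                     # average ranks handle ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

validation_report <- function(per_gene, excluded, parameters = list()) {
  included <- per_gene$auroc[!(per_gene$gene %in% excluded) &
                               !is.na(per_gene$auroc)]
  structure(list(per_gene = per_gene, excluded = excluded,
                 average_auroc = if (length(included)) mean(included) else NA_real_,
                 parameters = parameters),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report: ", nrow(x$per_gene), " reference genes, ",
      "average AUROC (", nrow(x$per_gene) - length(x$excluded),
      " included) = ", round(x$average_auroc, 3), "\n", sep = "")
  invisible(x)
}

# Shared machinery: source/target geodesics computed once from the full
# reference set; per-gene runs only rebuild the linear cost.
integration_context <- function(expr, map, ot, dist, source_genes = NULL,
                                top_n_corr = 100) {
  if (is.null(source_genes))
    source_genes <- select_reference_correlated_genes(expr, map,
                                                      top_n = top_n_corr)
  source_geo <- geodesic_distances(expr$values[, source_genes, drop = FALSE],
                                   k = ot$k_source)
  target_geo <- geodesic_distances(map$coords, k = ot$k_target)
  list(expr = expr, map = map, ot = ot, dist = dist,
       source_genes = source_genes, source_geo = source_geo,
       target_geo = target_geo)
}

run_integration <- function(ctx, exclude_genes = character(0)) {
  genes <- setdiff(ctx$map$ref_genes, exclude_genes)
  if (length(genes) == 0L) stop("no reference genes left for integration")
  prof <- reference_profiles(ctx$expr, ctx$map, ctx$dist,
                             exclude = exclude_genes)
  M <- pairwise_distance(prof, ctx$map$ref_expr[, genes, drop = FALSE],
                         ctx$dist)
  fused_gw_map(ctx$source_geo, ctx$target_geo, M, ctx$ot)
}

#' Leave-one-reference-gene-out AUROC validation
#'
#' For each reference gene, the integration is repeated with that gene's
#' column removed from the spatial map; the gene's snRNA-seq expression is
#' then projected onto the cells and scored by AUROC against the gene's
#' binary truth column in the map. Nucleus filters and the geodesic graphs
#' are computed once from the full reference set so the evaluated universe
#' stays constant across genes; only the linear cost excludes the held-out
#' gene.
#'
#' @param expr the filtered, prefiltered `expression_matrix`.
#' @param map the final `spatial_map`.
#' @param ot an `ot_config`.
#' @param dist a `distance_config`.
#' @param exclude genes reported per-gene but left out of the average (genes
#'   known to be unpredictable from the remaining set, or expressed in too
#'   few cells).
#' @param source_genes optional precomputed gene set for the nucleus graph;
#'   computed by [select_reference_correlated_genes()] when NULL.
#' @param top_n_corr per-reference list size for the gene selection.
#' @return a `validation_report` with per-gene AUROC (NA where the truth
#'   column is single-class) and the average over included genes.
#' @export
loocv_reference_genes <- function(expr, map, ot = ot_config(),
                                  dist = distance_config("jaccard"),
                                  exclude = character(0),
                                  source_genes = NULL, top_n_corr = 100) {
  ctx <- integration_context(expr, map, ot, dist, source_genes, top_n_corr)
  res <- lapply(map$ref_genes, function(g) {
    truth <- map$ref_expr[, g]
    if (length(unique(truth)) == 1L) {
      warning("reference gene ", g, " has a single-class truth column; NA")
      return(NA_real_)
    }
    plan <- run_integration(ctx, exclude_genes = g)
    atlas <- project_expression(plan, expr, genes = g)
    auroc(atlas$values[, g], truth)
  })
  per_gene <- data.frame(gene = map$ref_genes,
                         auroc = unlist(res),
                         stringsAsFactors = FALSE)
  validation_report(per_gene, exclude,
                    parameters = list(ot = unclass(ot), dist = unclass(dist),
                                      n_nuclei = length(expr$barcodes)))
}

#' PEP (predicted estimation performance) scores
#'
#' A gene can only be placed well if its expression co-varies with at least
#' one reference gene. The PEP score of a gene is the maximum Spearman
#' correlation of its expression with any *other* reference gene across the
#' (prefiltered) nuclei. Being computed purely in expression space, PEP
#' predicts reconstruction quality before any spatial data is used.
#'
#' @param expr the post-prefilter `expression_matrix`.
#' @param reference character vector of reference-gene identifiers (must be
#'   in `expr`).
#' @param genes genes to score; default all genes in `expr`.
#' @return an object of class `pep_table`: data.frame (`gene`, `pep`) plus
#'   attributes `reference` and `n_nuclei`. Constant genes get NA.
#' @export
pep_scores <- function(expr, reference, genes = NULL) {
  validate_expression_matrix(expr)
  missing <- setdiff(reference, expr$genes)
  if (length(missing))
    stop("reference gene(s) absent: ", paste(missing, collapse = ", "))
  if (is.null(genes)) genes <- expr$genes
  X <- expr$values[, genes, drop = FALSE]
  R <- expr$values[, reference, drop = FALSE]
  rho <- suppressWarnings(stats::cor(X, R, method = "spearman"))
  pep <- vapply(seq_along(genes), function(i) {
    r <- rho[i, setdiff(reference, genes[i])]
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(gene = genes, pep = pep, stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  attr(out, "n_nuclei") <- length(expr$barcodes)
  class(out) <- c("pep_table", class(out))
  out
}

#' PEP threshold from the PEP-AUROC relationship
#'
#' Reference genes are sorted by PEP and grouped into `bins` roughly
#' equal-sized bins; the threshold is the smallest PEP in the first bin from
#' which the binned mean AUROC exceeds 0.5 and stays above 0.5 in all later
#' bins. When the curve never crosses persistently, the configured default
#' is returned with a warning.
#'
#' @param pep a `pep_table`.
#' @param report a `validation_report` for the same reference genes.
#' @param bins number of bins along the PEP axis.
#' @param default fallback threshold (the value used for the floral
#'   meristem, 0.13).
#' @param allow_default_on_few with fewer than 3 usable genes, return the
#'   default instead of erroring.
#' @return a single PEP threshold.
#' @export
pep_threshold <- function(pep, report, bins = 10, default = 0.13,
                          allow_default_on_few = FALSE) {
  df <- merge(pep[, c("gene", "pep")], report$per_gene, by = "gene")
  df <- df[!is.na(df$pep) & !is.na(df$auroc), ]
  if (nrow(df) < 3) {
    if (allow_default_on_few) {
      warning("fewer than 3 usable genes; returning default threshold")
      return(default)
    }
    stop("fewer than 3 reference genes with both PEP and AUROC")
  }
  df <- df[order(df$pep), ]
  bins <- min(bins, nrow(df))
  bin_of <- ceiling(seq_len(nrow(df)) * bins / nrow(df))
  means <- tapply(df$auroc, bin_of, mean)
  above <- means > 0.5
  persistent <- rev(cumprod(rev(above))) == 1
  if (!any(persistent)) {
    warning("binned AUROC never stabilizes above 0.5; returning default ",
            default)
    return(default)
  }
  first <- min(which(persistent))
  min(df$pep[bin_of == first])
}

#' Sequential elimination of reference genes
#'
#' Removes reference genes from the spatial map one at a time — in
#' descending or ascending order of their maximum Spearman correlation to
#' the other reference genes — and records, after each removal, the AUROC
#' of the genes removed so far, each predicted from the reduced map.
#' Step 0 (nothing removed) is the full leave-one-out baseline of
#' [loocv_reference_genes()]. Removing the most-correlated genes first
#' strips each evaluated gene of its best correlates, so its reconstruction
#' degrades; removing the least-correlated first leaves the correlates in
#' place and the trajectory stays comparatively flat.
#'
#' @param expr,map,ot,dist as in [loocv_reference_genes()].
#' @param order `"desc"` (most-correlated first) or `"asc"`.
#' @param steps number of removal steps; default leaves at least 2 genes.
#' @param probe genes over which the step-0 baseline is averaged; default
#'   all reference genes.
#' @param source_genes,top_n_corr as in [loocv_reference_genes()].
#' @return data.frame with columns `step`, `removed_gene`, `mean_auroc`
#'   (mean over the genes removed so far; at step 0 over `probe`), plus
#'   attribute `per_gene` (reference-gene x step AUROC matrix, NA where a
#'   gene is still part of the map).
#' @export
sequential_elimination <- function(expr, map, ot = ot_config(),
                                   dist = distance_config("jaccard"),
                                   order = c("desc", "asc"), steps = NULL,
                                   probe = NULL, source_genes = NULL,
                                   top_n_corr = 100) {
  order <- match.arg(order)
  if (length(map$ref_genes) < 3) stop("need at least 3 reference genes")
  if (is.null(probe)) probe <- map$ref_genes
  if (is.null(steps)) steps <- length(map$ref_genes) - 2L
  steps <- min(steps, length(map$ref_genes) - 2L)

  ref_pep <- pep_scores(expr, reference = map$ref_genes,
                        genes = map$ref_genes)
  ord <- order(ref_pep$pep, ref_pep$gene,
               decreasing = (order == "desc"), method = "radix")
  removal <- ref_pep$gene[ord]

  ctx <- integration_context(expr, map, ot, dist, source_genes, top_n_corr)
  base <- loocv_reference_genes(expr, map, ot, dist, exclude = character(0),
                                source_genes = ctx$source_genes)
  base_auroc <- stats::setNames(base$per_gene$auroc, base$per_gene$gene)

  per_gene <- matrix(NA_real_, nrow = length(map$ref_genes),
                     ncol = steps + 1,
                     dimnames = list(map$ref_genes, paste0("step", 0:steps)))
  mean_traj <- numeric(steps + 1)
  mean_traj[1] <- mean(base_auroc[probe], na.rm = TRUE)
  per_gene[names(base_auroc), 1] <- base_auroc
  for (s in seq_len(steps)) {
    removed <- removal[seq_len(s)]
    plan <- run_integration(ctx, exclude_genes = removed)
    atlas <- project_expression(plan, expr, genes = removed)
    for (g in removed) {
      truth <- map$ref_expr[, g]
      if (length(unique(truth)) == 1L) next
      per_gene[g, s + 1] <- auroc(atlas$values[, g], truth)
    }
    mean_traj[s + 1] <- mean(per_gene[removed, s + 1], na.rm = TRUE)
  }
  out <- data.frame(step = 0:steps,
                    removed_gene = c(NA, removal[seq_len(steps)]),
                    mean_auroc = mean_traj,
                    stringsAsFactors = FALSE)
  attr(out, "per_gene") <- per_gene
  attr(out, "order") <- order
  out
}

#' Pseudobulk agreement with bulk RNA-seq
#'
#' Pools the single-nucleus matrix by summing each gene over all nuclei and
#' correlates the pooled profile with an external bulk profile on shared
#' genes, after `log2(x + 1)` transform of both.
#'
#' @param expr an `expression_matrix`.
#' @param bulk named numeric vector of bulk expression keyed by gene.
#' @return Pearson correlation over shared genes (requires >= 3).
#' @export
pseudobulk_correlation <- function(expr, bulk) {
  validate_expression_matrix(expr)
  shared <- intersect(expr$genes, names(bulk))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  pooled <- colSums(expr$values[, shared, drop = FALSE])
  stats::cor(log2(pooled + 1), log2(bulk[shared] + 1))
}
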