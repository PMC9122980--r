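#' Full reconstruction pipeline
#'
#' Runs the complete integration in the published order: spatial-map filters
#' (cells with no reference expression; uninformative reference genes; cells
#' with few genes or rare combinations), snRNA-seq filters (low-prevalence
#' genes with a protected list; nuclei expressing no final reference gene),
#' reference-correlated gene selection, the top-k nucleus prefilter,
#' geodesic graph construction on both sides, the fused entropic
#' Gromov-Wasserstein solve, and projection of the full transcriptomes onto
#' the map.
#'
#' @param expr a normalized `expression_matrix`.
#' @param map a `spatial_map`.
#' @param ot an `ot_config` (defaults are the published parameter set).
#' @param dist a `distance_config`; Jaccard by default.
#' @param top_n_corr per-reference top list size for the source-graph gene
#'   selection.
#' @param min_prevalence,keep_genes low-prevalence gene filter settings.
#' @param genes genes to project; default all genes surviving the filters.
#' @param apply_filters run the filter cascade? Set FALSE when inputs are
#'   already filtered.
#' @param out_dir if given, atlas, plan and a JSON run manifest are written
#'   there.
#' @return list with `atlas`, `plan` (unscaled), `scaled_plan`, `map`
#'   (filtered), `expr` (retained nuclei), `source_genes`, `reports` (filter
#'   reports), `ot`, `dist`.
#' @export
reconstruct_atlas <- function(expr, map, ot = ot_config(),
                              dist = distance_config("jaccard"),
                              top_n_corr = 100, min_prevalence = 30,
                              keep_genes = character(0), genes = NULL,
                              apply_filters = TRUE, out_dir = NULL) {
  reports <- list()
  if (apply_filters) {
    st <- filter_cells_no_reference(map)
    map <- st$map; reports$cells_no_reference <- st$report
    st <- filter_uninformative_reference_genes(map, expr)
    map <- st$map; reports$uninformative_genes <- st$report
    st <- filter_sparse_and_rare_combination_cells(map)
    map <- st$map; reports$sparse_rare_cells <- st$report
    st <- filter_low_prevalence_genes(expr, min_cells = min_prevalence,
                                      always_keep = keep_genes)
    expr <- st$expr; reports$low_prevalence_genes <- st$report
    st <- filter_nuclei_no_reference(expr, map)
    expr <- st$expr; reports$nuclei_no_reference <- st$report
  }
  st <- prefilter_top_k_nuclei(expr, map, config = dist, k = ot$top_k_filter)
  expr <- st$expr; reports$top_k_nuclei <- st$report

  source_genes <- select_reference_correlated_genes(expr, map,
                                                    top_n = top_n_corr)
  ctx <- integration_context(expr, map, ot, dist,
                             source_genes = source_genes)
  plan <- run_integration(ctx)
  atlas <- project_expression(plan, expr, genes = genes)
  scaled <- scale_plan(plan, ot$plan_scale)

  res <- list(atlas = atlas, plan = plan, scaled_plan = scaled, map = map,
              expr = expr, source_genes = source_genes, reports = reports,
              ot = ot, dist = dist)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_atlas(atlas, map, out_dir)
    write_plan(scaled, out_dir)
    manifest <- list(
      parameters = list(ot = unclass(ot), dist = unclass(dist),
                        top_n_corr = top_n_corr,
                        min_prevalence = min_prevalence,
                        keep_genes = keep_genes),
      filters = lapply(reports, function(r)
        list(stage = r$stage, items_removed = r$items_removed)),
      n_cells = n_cells(map), n_nuclei = length(expr$barcodes),
      n_source_genes = length(source_genes),
      converged = plan$converged, iterations = plan$iterations)
    write_run_manifest(manifest, file.path(out_dir, "run_manifest.json"))
  }
  res
}
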