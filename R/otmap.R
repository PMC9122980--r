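#' Solver configuration for the fused Gromov-Wasserstein mapping
#'
#' Defaults are the parameter set used for the floral-meristem
#' reconstruction: `num_neighbors_source = 2`, `num_neighbors_target = 5`,
#' `epsilon = 0.05`, `alpha = 0.1`, `max_iter = 5000`, `tol = 1e-9`, a
#' top-50 nucleus prefilter, and a plan export multiplier of 1e5.
#'
#' @param alpha weight of the linear reference-gene cost in \[0, 1\]; the
#'   structural (quadratic) term gets weight `1 - alpha`.
#' @param epsilon entropic regularization strength (> 0).
#' @param max_iter outer iteration cap.
#' @param tol convergence tolerance on the elementwise plan change.
#' @param k_source,k_target kNN sizes for the nucleus and spatial-cell
#'   geodesic graphs.
#' @param top_k_filter nuclei kept per spatial cell by the prefilter
#'   (0 disables).
#' @param plan_scale export multiplier applied by [scale_plan()].
#' @return an object of class `ot_config`.
#' @export
ot_config <- function(alpha = 0.1, epsilon = 0.05, max_iter = 5000,
                      tol = 1e-9, k_source = 2, k_target = 5,
                      top_k_filter = 50, plan_scale = 1e5) {
  stopifnot(alpha >= 0, alpha <= 1, epsilon > 0, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, epsilon = epsilon,
                 max_iter = as.integer(max_iter), tol = tol,
                 k_source = as.integer(k_source),
                 k_target = as.integer(k_target),
                 top_k_filter = as.integer(top_k_filter),
                 plan_scale = plan_scale),
            class = "ot_config")
}

#' Construct a transport plan
#'
#' Container for the probabilistic nucleus-to-cell assignment (the "GW
#' matrix"): `T[i, j]` is the coupling mass between nucleus i and spatial
#' cell j. Normally produced by [fused_gw_map()].
#'
#' @param T nuclei x cells non-negative matrix.
#' @param p,q row and column marginals.
#' @param iterations,final_change,converged convergence record.
#' @param scaled,scale export-scaling state (see [scale_plan()]).
#' @return an object of class `transport_plan`.
#' @export
transport_plan <- function(T, p, q, iterations, final_change, converged,
                           scaled = FALSE, scale = 1) {
  structure(list(T = T, p = p, q = q, iterations = iterations,
                 final_change = final_change, converged = converged,
                 scaled = scaled, scale = scale),
            class = "transport_plan")
}

#' @export
print.transport_plan <- function(x, ...) {
  cat("transport_plan: ", nrow(x$T), " nuclei x ", ncol(x$T), " cells, ",
      x$iterations, " iterations",
      if (!x$converged) " (NOT converged)",
      if (x$scaled) paste0(", scaled by ", format(x$scale)), "\n", sep = "")
  invisible(x)
}

#' Construct a reconstructed atlas
#'
#' @param values cells x genes non-negative matrix of predicted expression.
#' @param cell_ids cell identifiers in spatial-map order.
#' @param genes gene identifiers.
#' @param provenance optional list (configs, checksums) carried along.
#' @return an object of class `reconstructed_atlas`.
#' @export
reconstructed_atlas <- function(values, cell_ids = rownames(values),
                                genes = colnames(values), provenance = NULL) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(values)))
  dimnames(values) <- list(cell_ids, genes)
  if (any(values < 0, na.rm = TRUE))
    stop("validation error: negative predicted expression")
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 genes = as.character(genes), provenance = provenance),
            class = "reconstructed_atlas")
}

#' @export
print.reconstructed_atlas <- function(x, ...) {
  cat("reconstructed_atlas: ", length(x$cell_ids), " cells x ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Keep only nuclei close to the spatial map (top-k prefilter)
#'
#' Dissociated material can contain nuclei from regions absent from the
#' spatial map. For each spatial cell the `k` nuclei with the closest
#' reference-gene profile are found, and the union of these per-cell sets is
#' retained; everything else is discarded. Ties at rank `k` are all kept.
#'
#' @param expr an `expression_matrix` containing the map's reference genes.
#' @param map the final `spatial_map`.
#' @param config a `distance_config`; jaccard by default (the setting used
#'   for the floral meristem).
#' @param k nuclei kept per spatial cell; `k <= 0` or `k >=` number of
#'   nuclei disables the filter.
#' @return list with elements `expr` (retained nuclei, order preserved) and
#'   `report`.
#' @export
prefilter_top_k_nuclei <- function(expr, map,
                                   config = distance_config("jaccard"),
                                   k = 50) {
  validate_expression_matrix(expr)
  n <- length(expr$barcodes)
  if (k <= 0 || k >= n) {
    return(list(expr = expr,
                report = filter_report("top_k_nuclei", character(0),
                                       list(k = k, metric = config$metric))))
  }
  prof <- reference_profiles(expr, map, config)
  D <- pairwise_distance(prof, map$ref_expr, config)
  keep <- rep(FALSE, n)
  for (j in seq_len(ncol(D))) {
    kth <- sort(D[, j], partial = k)[k]
    keep <- keep | (D[, j] <= kth)
  }
  list(expr = subset_expression(expr, nuclei = keep),
       report = filter_report("top_k_nuclei", expr$barcodes[!keep],
                              list(k = k, metric = config$metric)))
}

# Nuclei x reference-genes profiles in map gene order, binarized when the
# metric demands it.
reference_profiles <- function(expr, map, config, exclude = character(0)) {
  genes <- setdiff(map$ref_genes, exclude)
  missing <- setdiff(genes, expr$genes)
  if (length(missing))
    stop("reference gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  P <- expr$values[, genes, drop = FALSE]
  if (config$binarize_sc) P <- (P > 0) + 0
  P
}

#' Fused entropic Gromov-Wasserstein transport between nuclei and cells
#'
#' Finds a soft assignment `T` (nuclei x spatial cells) minimizing
#' \deqn{J(T) = \alpha \sum_{ij} M_{ij} T_{ij} +
#'   (1-\alpha) \sum_{ijkl} (D^s_{ik} - D^t_{jl})^2 T_{ij} T_{kl}
#'   - \epsilon H(T)}
#' over couplings with uniform marginals (`T 1 = p`, `T' 1 = q`,
#' `p_i = 1/n`, `q_j = 1/m`), where `M` is the linear reference-gene cost
#' (max-rescaled to \[0,1\]), `D^s`/`D^t` the source/target geodesic
#' matrices and `H` the entropy. The quadratic term is handled by iterated
#' linearization (square-loss gradient) followed by an entropic scaling
#' (Sinkhorn) projection onto the coupling polytope. The solver is
#' deterministic: it starts from the independent coupling `T = p q'` and
#' stops when the elementwise plan change drops to `tol` or `max_iter` is
#' reached.
#'
#' @param source_geo `geodesic_matrix` over nuclei.
#' @param target_geo `geodesic_matrix` over spatial cells.
#' @param linear_cost nuclei x cells non-negative cost matrix; rescaled
#'   internally to \[0, 1\] by its maximum.
#' @param config an `ot_config`.
#' @return a `transport_plan`; if the iteration cap is hit before the
#'   tolerance, the plan is returned with `converged = FALSE` and a warning.
#' @export
fused_gw_map <- function(source_geo, target_geo, linear_cost,
                         config = ot_config()) {
  Ds <- source_geo$D
  Dt <- target_geo$D
  M <- as.matrix(linear_cost)
  n <- nrow(M); m <- ncol(M)
  stopifnot(nrow(Ds) == n, nrow(Dt) == m)
  if (any(!is.finite(M)) || any(!is.finite(Ds)) || any(!is.finite(Dt)))
    stop("NaN/Inf in cost inputs")
  if (any(M < 0)) stop("linear cost must be non-negative")
  if (max(M) > 0) M <- M / max(M)

  p <- rep(1 / n, n)
  q <- rep(1 / m, m)
  alpha <- config$alpha
  eps <- config$epsilon

  # square-loss decomposition of the quadratic term:
  # grad(T) = constC - 2 Ds T Dt  (up to the factor 2 absorbed in h2)
  constC <- outer(as.vector((Ds^2) %*% p), rep(1, m)) +
    outer(rep(1, n), as.vector((Dt^2) %*% q))

  T_cur <- tcrossprod(p, q)
  iterations <- 0L
  delta <- Inf
  for (it in seq_len(config$max_iter)) {
    iterations <- it
    G <- if (alpha < 1) {
      tens <- constC - 2 * Ds %*% T_cur %*% Dt
      alpha * M + (1 - alpha) * tens
    } else {
      M
    }
    T_new <- sinkhorn_scaling(G, p, q, eps)
    delta <- max(abs(T_new - T_cur))
    T_cur <- T_new
    if (delta <= config$tol) break
  }
  converged <- delta <= config$tol
  if (!converged)
    warning("fused_gw_map did not reach tol = ", config$tol, " after ",
            config$max_iter, " iterations (last change ",
            signif(delta, 3), ")")
  dimnames(T_cur) <- dimnames(linear_cost)
  transport_plan(T_cur, p, q, iterations, delta, converged)
}

# Entropic projection: argmin <G,T> - eps H(T) s.t. marginals (p, q).
# Standard Sinkhorn iterations on the Gibbs kernel; G is shifted by its
# minimum, which only rescales the kernel and improves conditioning.
sinkhorn_scaling <- function(G, p, q, eps, max_iter = 1000, tol = 1e-9) {
  K <- exp(-(G - min(G)) / eps)
  v <- rep(1, length(q))
  u <- rep(1, length(p))
  for (it in seq_len(max_iter)) {
    u <- p / pmax(K %*% v, .Machine$double.xmin)
    v <- q / pmax(crossprod(K, u), .Machine$double.xmin)
    if (it %% 10 == 0) {
      err <- max(abs(u * (K %*% v) - p))
      if (err <= tol) break
    }
  }
  K * outer(as.vector(u), as.vector(v))
}

#' Rescale a transport plan for export
#'
#' The raw coupling has tiny entries (order 1/(n m)); for export the matrix
#' is multiplied by a large factor so values are readable. Downstream
#' probabilistic operations renormalize columns, so the factor cancels.
#'
#' @param plan an unscaled `transport_plan`.
#' @param factor multiplier (default 1e5).
#' @return the scaled `transport_plan` (total mass = factor).
#' @export
scale_plan <- function(plan, factor = 1e5) {
  stopifnot(inherits(plan, "transport_plan"))
  if (plan$scaled) stop("plan already scaled")
  plan$T <- plan$T * factor
  plan$scaled <- TRUE
  plan$scale <- factor
  plan
}

#' Project full transcriptomes onto the spatial map
#'
#' Each spatial cell's predicted expression is the conditional mean of the
#' nucleus expression given that cell: the plan's columns are renormalized
#' to sum to 1 and the prediction for gene g at cell j is
#' `sum_i That_ij * X_ig`. Column renormalization makes the prediction
#' invariant to the plan's scale and to the number of nuclei.
#'
#' @param plan a `transport_plan` whose rows align with `expr`'s nuclei.
#' @param expr an `expression_matrix`.
#' @param genes genes to project; default all genes in `expr`.
#' @return a `reconstructed_atlas` (cells x genes).
#' @export
project_expression <- function(plan, expr, genes = NULL) {
  validate_expression_matrix(expr)
  T <- plan$T
  if (nrow(T) != length(expr$barcodes))
    stop("alignment mismatch: plan rows != number of nuclei")
  if (!is.null(rownames(T)) && !identical(rownames(T), expr$barcodes))
    stop("alignment mismatch: plan row names differ from barcodes")
  if (is.null(genes)) genes <- expr$genes
  missing <- setdiff(genes, expr$genes)
  if (length(missing))
    stop("gene(s) not in expression matrix: ", paste(missing, collapse = ", "))
  cols <- colSums(T)
  if (any(cols <= 0))
    warning("transport plan has empty columns; predictions there are NA")
  That <- sweep(T, 2, ifelse(cols > 0, cols, 1), "/")
  vals <- crossprod(That, expr$values[, genes, drop = FALSE])
  vals[rep(cols <= 0, times = length(genes))] <- NA_real_
  reconstructed_atlas(vals, cell_ids = colnames(T), genes = genes)
}
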