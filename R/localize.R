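#' Localize an external transcriptomic signature on the spatial map
#'
#' Correlates a bulk signature (e.g. a FANS-sorted vascular stem-cell
#' profile) with the predicted transcriptome of every spatial cell, over a
#' supplied marker gene set. Both sides are `log2(x + 1)`-transformed and
#' per-gene mean-centered (across cells for the atlas; across samples for a
#' multi-sample signature) before computing, for each cell, the Pearson
#' correlation over the marker genes. One-sided p-values test whether the
#' correlation is greater than zero via the exact t transform
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom;
#' optionally a seeded gene-label permutation p-value is computed instead.
#'
#' @param atlas a `reconstructed_atlas` (full predicted transcriptomes or
#'   reference profiles).
#' @param signature named numeric vector (one sample) or genes x samples
#'   matrix; the first sample/column is localized.
#' @param markers character vector of marker genes to restrict to.
#' @param permutations if > 0, also compute permutation p-values with this
#'   many gene-label shuffles.
#' @param seed RNG seed for the permutations.
#' @return an object of class `localization_result` with a data.frame
#'   `per_cell` (`cell_id`, `r`, `p`, optionally `p_perm`) and `n_genes`,
#'   `markers` used.
#' @export
signature_localization <- function(atlas, signature, markers,
                                   permutations = 0, seed = 1) {
  if (is.matrix(signature) || is.data.frame(signature)) {
    signature <- as.matrix(signature)
    sig_genes <- rownames(signature)
    sig_mat <- log2(signature + 1)
    if (ncol(sig_mat) >= 2) sig_mat <- sweep(sig_mat, 1, rowMeans(sig_mat))
    sig <- sig_mat[, 1]
  } else {
    sig_genes <- names(signature)
    sig <- log2(signature + 1)
  }
  shared <- Reduce(intersect, list(atlas$genes, sig_genes, markers))
  if (length(shared) < 3)
    stop("fewer than 3 shared marker genes between atlas and signature")
  A <- log2(atlas$values[, shared, drop = FALSE] + 1)
  A <- sweep(A, 2, colMeans(A))           # per-gene centering across cells
  s <- sig[shared]
  r <- as.vector(stats::cor(t(A), s))
  nmk <- length(shared)
  p <- r_to_p_onesided(r, nmk)

  out <- data.frame(cell_id = atlas$cell_ids, r = r, p = p,
                    stringsAsFactors = FALSE)
  if (permutations > 0) {
    set.seed(seed)
    ge <- vapply(seq_len(permutations), function(i) {
      rp <- as.vector(stats::cor(t(A), s[sample.int(nmk)]))
      rp
    }, numeric(length(r)))
    out$p_perm <- (rowSums(ge >= r) + 1) / (permutations + 1)
  }
  structure(list(per_cell = out, n_genes = nmk, markers = shared,
                 mode = "signature"),
            class = "localization_result")
}

# One-sided upper-tail p for H1: rho > 0, exact t transform.
r_to_p_onesided <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  edge_hi <- ok & r >= 1 - 1e-15
  edge_lo <- ok & r <= -1 + 1e-15
  mid <- ok & !edge_hi & !edge_lo
  t_stat <- r[mid] * sqrt(n - 2) / sqrt(1 - r[mid]^2)
  p[mid] <- stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
  p[edge_hi] <- 0
  p[edge_lo] <- 1
  p
}

#' Localize snRNA-seq clusters on the spatial map
#'
#' The transport plan is column-normalized so each spatial cell's column
#' sums to 1; a cell's score for a cluster is then the summed probability
#' of all nuclei belonging to that cluster. Scores over clusters therefore
#' sum to 1 per cell, and any uniform scaling of the plan cancels. Nuclei
#' without a label are grouped as `"unassigned"`.
#'
#' @param plan a `transport_plan` (scaled or not).
#' @param labels named vector of cluster ids keyed by nucleus barcode (see
#'   [read_cluster_labels()]), or an unnamed vector aligned with plan rows.
#' @return a `localization_result` with `scores`: cells x clusters matrix
#'   (rows sum to 1; NA rows for cells receiving no mass).
#' @export
cluster_localization <- function(plan, labels) {
  T <- plan$T
  n <- nrow(T)
  if (is.null(names(labels))) {
    if (length(labels) != n)
      stop("unnamed labels must align with plan rows")
    lab <- as.character(labels)
  } else {
    lab <- as.character(labels[rownames(T)])
  }
  lab[is.na(lab)] <- "unassigned"
  cols <- colSums(T)
  zero <- cols <= 0
  if (any(zero))
    warning(sum(zero), " spatial cell(s) receive no mass; scores are NA")
  That <- sweep(T, 2, ifelse(zero, 1, cols), "/")
  lev <- sort(unique(lab))
  ind <- vapply(lev, function(l) (lab == l) + 0, numeric(n))
  colnames(ind) <- lev
  scores <- crossprod(That, ind)        # cells x clusters
  scores[zero, ] <- NA_real_
  rownames(scores) <- colnames(T)
  structure(list(scores = scores, mode = "clusters"),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  if (x$mode == "signature") {
    cat("localization_result (signature): ", nrow(x$per_cell), " cells, ",
        x$n_genes, " marker genes; max r = ",
        round(max(x$per_cell$r), 3), "\n", sep = "")
  } else {
    cat("localization_result (clusters): ", nrow(x$scores), " cells x ",
        ncol(x$scores), " clusters\n", sep = "")
  }
  invisible(x)
}
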