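#' @title Synthetic dome meristem with known ground truth
#' @description
#' Generators that emulate the two inputs of the pipeline: a dome-shaped 3D
#' cell arrangement carrying layered/sectored binary reference-gene domains,
#' and single-nucleus transcriptomes whose expression is a noisy,
#' dropout-corrupted function of each nucleus's true position. Every stage
#' of the pipeline can thus be tested against a known truth without any
#' external download.
#' @name synthdata
NULL

# Region archetypes painted onto the dome. r = distance from the dome
# center, rho = cylindrical radius, th = azimuth. Regions overlap (shell and
# sub-shell layers, core and axis, sector and half-dome), giving the
# reference set the graded redundancy real marker sets have: some genes have
# well-correlated partners, others carry mostly unique information.
.region_catalog <- function(R) {
  list(
    SHELL    = function(x, y, z, r, rho, th) r >= 0.78 * R,       # L1-like
    SUBSHELL = function(x, y, z, r, rho, th) r >= 0.55 * R & r < 0.88 * R,
    CORE     = function(x, y, z, r, rho, th) r < 0.62 * R,
    AXIS     = function(x, y, z, r, rho, th) rho < 0.45 * R,
    APEX     = function(x, y, z, r, rho, th) z >= 0.5 * R,
    EAST     = function(x, y, z, r, rho, th) x >= -0.1 * R,       # sector
    SECT2    = function(x, y, z, r, rho, th) cos(2 * th) >= -0.2, # whorl-like
    BASEPERI = function(x, y, z, r, rho, th) z < 0.4 * R & rho >= 0.35 * R,
    NORTH    = function(x, y, z, r, rho, th) y >= -0.1 * R,
    ANNULUS  = function(x, y, z, r, rho, th) rho >= 0.3 * R & rho < 0.75 * R,
    WESTBASE = function(x, y, z, r, rho, th) x < 0.1 * R | z < 0.3 * R,
    RING     = function(x, y, z, r, rho, th) r >= 0.4 * R & r < 0.85 * R
  )
}

#' Generate a synthetic dome-shaped spatial map
#'
#' Cell centers are sampled quasi-uniformly inside a hemispherical dome and
#' binary reference domains of three archetypes are painted on them: an
#' outer shell (epidermis-like), central core/axis regions, and azimuthal
#' sectors/annuli (whorl-like). A deterministic repair pass then reassigns
#' any cell whose pattern would fail the spatial-map filters, so that under
#' defaults every cell expresses at least `min_genes` reference genes and
#' every binary pattern is shared by at least `min_multiplicity` cells.
#'
#' @param n_cells number of cells (>= 50).
#' @param n_ref_genes number of reference genes (4..12).
#' @param geometry only `"dome"` is implemented.
#' @param seed RNG seed; output is bit-identical for equal seeds.
#' @param radius dome radius (unitless; think micrometres).
#' @param min_genes,min_multiplicity constraints enforced by the repair
#'   pass (matching the defaults of the spatial-map filters).
#' @return list with elements `map` (a `spatial_map`) and `truth` (a
#'   `synthetic_truth` carrying the painted patterns, per-gene archetypes
#'   and generation parameters).
#' @export
make_meristem_map <- function(n_cells = 300, n_ref_genes = 8,
                              geometry = "dome", seed = 1, radius = 50,
                              min_genes = 3, min_multiplicity = 5) {
  geometry <- match.arg(geometry, "dome")
  if (n_cells < 50) stop("n_cells must be >= 50")
  if (n_ref_genes < 4) stop("n_ref_genes must be >= 4")
  catalog <- .region_catalog(radius)
  if (n_ref_genes > length(catalog))
    stop("constraints unsatisfiable: at most ", length(catalog),
         " reference genes supported")
  set.seed(seed)

  # rejection sampling of the hemisphere interior
  coords <- matrix(NA_real_, n_cells, 3)
  filled <- 0
  while (filled < n_cells) {
    cand <- matrix(stats::runif(3 * 2 * n_cells, -radius, radius), ncol = 3)
    cand[, 3] <- abs(cand[, 3])
    ok <- sqrt(rowSums(cand^2)) <= radius
    take <- min(sum(ok), n_cells - filled)
    coords[filled + seq_len(take), ] <- cand[ok, , drop = FALSE][seq_len(take), ]
    filled <- filled + take
  }
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  r <- sqrt(x^2 + y^2 + z^2)
  rho <- sqrt(x^2 + y^2)
  th <- atan2(y, x)

  regions <- catalog[seq_len(n_ref_genes)]
  gene_names <- paste0("REF", seq_len(n_ref_genes))
  raw <- vapply(regions, function(f) f(x, y, z, r, rho, th) + 0,
                numeric(n_cells))
  colnames(raw) <- gene_names

  # Spatially quantized painting: cells are grouped into contiguous
  # neighbourhoods (k-means on coordinates, ~2x the multiplicity floor per
  # group) and each group is painted by the majority vote of its members per
  # gene. All cells of a group share one pattern, so pattern multiplicity is
  # bounded below by the group size — mirroring how real expression domains
  # are contiguous blocks of cells, not per-cell salt-and-pepper.
  n_groups <- max(4L, min(floor(n_cells / (1.2 * min_multiplicity)), 48L))
  km <- stats::kmeans(coords, centers = n_groups, nstart = 5, iter.max = 100)
  grp <- km$cluster
  # fold undersized groups into their nearest neighbour group
  repeat {
    sizes <- table(grp)
    small <- names(sizes)[sizes < min_multiplicity]
    if (length(small) == 0) break
    s <- as.integer(small[1])
    cent <- apply(coords, 2, function(v) tapply(v, grp, mean))
    others <- setdiff(rownames(cent), small[1])
    d2 <- colSums((t(cent[others, , drop = FALSE]) - cent[small[1], ])^2)
    grp[grp == s] <- as.integer(names(which.min(d2)))
  }
  grp <- match(grp, sort(unique(grp)))          # contiguous group ids
  n_grp <- max(grp)
  cover <- apply(raw, 2, function(v) tapply(v, grp, mean))  # group coverage
  cover <- matrix(cover, nrow = n_grp)
  P <- (cover >= 0.5) + 0                        # majority-vote pattern
  cent <- apply(coords, 2, function(v) tapply(v, grp, mean))

  for (pass in 1:5) {
    # a gene painted uniformly would be dropped by the uninformative-gene
    # filter; flip the group most (least) covered by the raw region
    for (j in seq_len(ncol(P))) {
      if (length(unique(P[, j])) > 1L) next
      if (all(P[, j] == 0)) {
        P[which.max(cover[, j]), j] <- 1
      } else {
        cand <- which(rowSums(P) > min_genes)
        if (length(cand) == 0)
          stop("constraints unsatisfiable for requested sizes")
        P[cand[which.min(cover[cand, j])], j] <- 0
      }
    }
    # groups expressing too few genes adopt the nearest richer pattern
    while (any(rowSums(P) < min_genes)) {
      bad <- which(rowSums(P) < min_genes)[1]
      ok <- which(rowSums(P) >= min_genes)
      if (length(ok) == 0)
        stop("constraints unsatisfiable for requested sizes")
      d2 <- colSums((t(cent[ok, , drop = FALSE]) - cent[bad, ])^2)
      P[bad, ] <- P[ok[which.min(d2)], ]
    }
    if (all(apply(P, 2, function(v) length(unique(v)) > 1L))) break
  }
  constant <- apply(P, 2, function(v) length(unique(v)) == 1L)
  if (any(constant))
    stop("constraints unsatisfiable: reference gene(s) became constant (",
         paste(gene_names[constant], collapse = ", "), ")")
  expr <- P[grp, , drop = FALSE]
  dimnames(expr) <- list(NULL, gene_names)

  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  map <- spatial_map(cell_ids, coords, gene_names, expr)
  truth <- structure(
    list(patterns = map$ref_expr, archetypes = stats::setNames(
           names(catalog)[seq_len(n_ref_genes)], gene_names),
         params = list(n_cells = n_cells, n_ref_genes = n_ref_genes,
                       geometry = geometry, seed = seed, radius = radius,
                       min_genes = min_genes,
                       min_multiplicity = min_multiplicity)),
    class = "synthetic_truth")
  list(map = map, truth = truth)
}

# Smooth non-negative spatial fields used for probe genes.
.probe_field <- function(type, map, truth, ref_gene = NULL) {
  R <- truth$params$radius
  x <- map$coords[, 1]; y <- map$coords[, 2]; z <- map$coords[, 3]
  r <- sqrt(x^2 + y^2 + z^2)
  switch(type,
    domain = 0.2 + 1.8 * map$ref_expr[, ref_gene],
    linear = {
      w <- stats::rnorm(3)
      w <- w / sqrt(sum(w^2))
      f <- as.vector(map$coords %*% w)
      2 * (f - min(f)) / max(f - min(f) + 1e-12)
    },
    radial = 2 * (1 - r / R),
    noise = rep(0.5, nrow(map$coords)))
}

#' Simulate single-nucleus transcriptomes from a synthetic map
#'
#' Each genuine nucleus is assigned a true cell (uniformly over cells); its
#' reference-gene expression is the cell's binary pattern under lognormal
#' multiplicative noise and Bernoulli dropout, and its probe-gene expression
#' follows smooth spatial fields (domain-linked, linear or radial) or a
#' position-independent noise regime, corrupted the same way. A fraction of
#' contaminant nuclei is drawn from an unrelated regime with no
#' reference-gene structure, emulating dissociated material from tissue
#' outside the map. Values are then log-normalized (`log2(1 + x)`), so in
#' the noiseless limit a nucleus's reference profile equals its true cell's
#' binary pattern exactly.
#'
#' @param map,truth output of [make_meristem_map()].
#' @param n_nuclei total nuclei including contaminants.
#' @param n_probe_genes number of probe genes (40% domain-linked, 40% smooth
#'   spatial fields, 20% position-independent noise).
#' @param noise_sd sd of the lognormal noise on the log scale.
#' @param dropout probability that an entry is zeroed.
#' @param contaminant_frac fraction of contaminant nuclei.
#' @param seed RNG seed.
#' @return list with `expr` (an `expression_matrix`), `labels` (named
#'   cluster vector: 1 = shell-origin, 2 = axis-origin, 3 = other,
#'   0 = contaminant), and `truth` (a `synthetic_truth` extended with
#'   `nucleus_cell`, `probe_profiles`, `probe_types`).
#' @export
simulate_nuclei <- function(map, truth, n_nuclei = 1000, n_probe_genes = 50,
                            noise_sd = 0.3, dropout = 0.2,
                            contaminant_frac = 0.1, seed = 1) {
  stopifnot(noise_sd >= 0, dropout >= 0, dropout <= 1,
            contaminant_frac >= 0, contaminant_frac < 1)
  set.seed(seed)
  n_cells <- n_cells(map)
  n_cont <- round(contaminant_frac * n_nuclei)
  n_gen <- n_nuclei - n_cont
  true_cell <- c(sample.int(n_cells, n_gen, replace = TRUE),
                 rep(NA_integer_, n_cont))

  # probe gene truth: smooth spatial profiles on the map
  types <- rep(c("domain", "linear", "radial", "noise"),
               times = ceiling(n_probe_genes *
                                 c(0.4, 0.2, 0.2, 0.2)))[seq_len(n_probe_genes)]
  probe_names <- sprintf("PROBE%03d", seq_len(n_probe_genes))
  linked_ref <- sample(map$ref_genes, n_probe_genes, replace = TRUE)
  probe_profiles <- vapply(seq_len(n_probe_genes), function(j) {
    .probe_field(types[j], map, truth, ref_gene = linked_ref[j])
  }, numeric(n_cells))
  colnames(probe_profiles) <- probe_names
  rownames(probe_profiles) <- map$cell_ids

  noisy <- function(base) {
    v <- base * exp(matrix(stats::rnorm(length(base), 0, noise_sd),
                           nrow(base), ncol(base)))
    if (dropout > 0)
      v <- v * matrix(stats::rbinom(length(base), 1, 1 - dropout),
                      nrow(base), ncol(base))
    v
  }

  gen_ref <- noisy(map$ref_expr[true_cell[seq_len(n_gen)], , drop = FALSE])
  gen_probe <- noisy(probe_profiles[true_cell[seq_len(n_gen)], , drop = FALSE])
  if (n_cont > 0) {
    # unrelated regime: sparse random positivity, no spatial structure
    cont_ref <- noisy(matrix(stats::rbinom(n_cont * n_ref_genes(map), 1, 0.25),
                             n_cont, n_ref_genes(map)))
    cont_probe <- noisy(matrix(stats::rbinom(n_cont * n_probe_genes, 1, 0.3),
                               n_cont, n_probe_genes))
    values <- rbind(cbind(gen_ref, gen_probe), cbind(cont_ref, cont_probe))
  } else {
    values <- cbind(gen_ref, gen_probe)
  }
  values <- log2(1 + values)
  barcodes <- sprintf("nuc%05d", seq_len(n_nuclei))
  expr <- expression_matrix(values, barcodes = barcodes,
                            genes = c(map$ref_genes, probe_names))

  shell_gene <- names(truth$archetypes)[truth$archetypes == "SHELL"][1]
  axis_gene <- names(truth$archetypes)[truth$archetypes == "AXIS"][1]
  lab <- integer(n_nuclei)
  gen_idx <- seq_len(n_gen)
  in_shell <- map$ref_expr[true_cell[gen_idx], shell_gene] == 1
  in_axis <- map$ref_expr[true_cell[gen_idx], axis_gene] == 1
  lab[gen_idx] <- ifelse(in_shell, 1L, ifelse(in_axis, 2L, 3L))
  labels <- stats::setNames(lab, barcodes)

  truth$nucleus_cell <- stats::setNames(true_cell, barcodes)
  truth$probe_profiles <- probe_profiles
  truth$probe_types <- stats::setNames(types, probe_names)
  truth$params <- c(truth$params,
                    list(n_nuclei = n_nuclei, n_probe_genes = n_probe_genes,
                         noise_sd = noise_sd, dropout = dropout,
                         contaminant_frac = contaminant_frac,
                         nuclei_seed = seed))
  list(expr = expr, labels = labels, truth = truth)
}

#' Evaluate recovery of the synthetic ground truth
#'
#' Reports (i) the per-reference-gene held-out AUROC from a supplied
#' leave-one-out `validation_report` (truth columns equal the painted
#' patterns); (ii) per-probe-gene Spearman correlation between predicted and
#' true spatial profiles, plus AUROC against the midrange-binarized true
#' profile (NA for constant, position-independent probes); and (iii)
#' assignment accuracy, the fraction of genuine nuclei whose argmax plan
#' column lies within radius `rho` of their true cell.
#'
#' @param atlas a `reconstructed_atlas` containing probe genes.
#' @param plan the `transport_plan` from the same run.
#' @param truth the extended `synthetic_truth` from [simulate_nuclei()].
#' @param map the `spatial_map` (possibly filtered; matched by cell id).
#' @param report optional `validation_report` from
#'   [loocv_reference_genes()].
#' @param rho distance tolerance for assignment accuracy; default 1.5x the
#'   median nearest-neighbour spacing of the map.
#' @return list with `probe_table` (gene, type, spearman, auroc),
#'   `median_probe_spearman`, `assignment_accuracy`, `rho`, and (when
#'   `report` is given) `per_gene_auroc` and `mean_heldout_auroc`.
#' @export
evaluate_recovery <- function(atlas, plan, truth, map, report = NULL,
                              rho = NULL) {
  probes <- intersect(colnames(truth$probe_profiles), atlas$genes)
  cells <- match(atlas$cell_ids, rownames(truth$probe_profiles))
  probe_stats <- lapply(probes, function(g) {
    tp <- truth$probe_profiles[cells, g]
    pred <- atlas$values[, g]
    if (length(unique(tp)) == 1L)
      return(c(spearman = NA_real_, auroc = NA_real_))
    sp <- suppressWarnings(stats::cor(pred, tp, method = "spearman"))
    lab <- (tp > (min(tp) + max(tp)) / 2) + 0
    au <- if (length(unique(lab)) == 1L) NA_real_ else auroc(pred, lab)
    c(spearman = sp, auroc = au)
  })
  probe_table <- data.frame(
    gene = probes,
    type = truth$probe_types[probes],
    do.call(rbind, probe_stats),
    stringsAsFactors = FALSE, row.names = NULL)

  # assignment accuracy on genuine nuclei present in the plan
  bar <- rownames(plan$T)
  tc <- truth$nucleus_cell[bar]
  genuine <- !is.na(tc)
  if (is.null(rho)) {
    nn <- apply(as.matrix(stats::dist(map$coords)) +
                  diag(Inf, n_cells(map)), 1, min)
    rho <- 1.5 * stats::median(nn)
  }
  argmax_col <- max.col(plan$T[genuine, , drop = FALSE], ties.method = "first")
  pred_xyz <- map$coords[match(colnames(plan$T)[argmax_col],
                               map$cell_ids), , drop = FALSE]
  # true cell ids are row names of the (unfiltered) probe profile matrix
  true_xyz <- map$coords[match(rownames(truth$probe_profiles)[tc[genuine]],
                               map$cell_ids), , drop = FALSE]
  d <- sqrt(rowSums((pred_xyz - true_xyz)^2))
  accuracy <- mean(d <= rho, na.rm = TRUE)

  out <- list(probe_table = probe_table,
              median_probe_spearman =
                stats::median(probe_table$spearman, na.rm = TRUE),
              assignment_accuracy = accuracy, rho = rho)
  if (!is.null(report)) {
    out$per_gene_auroc <- report$per_gene
    out$mean_heldout_auroc <- report$average_auroc
  }
  out
}
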