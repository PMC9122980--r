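# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (double loops, direct formulas) and share no
# code with the functions they check.

# AUROC by brute-force enumeration of positive-negative pairs.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Pairwise distances by naive double loop.
dist_naive <- function(A, B, metric) {
  D <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    x <- A[i, ]; y <- B[j, ]
    D[i, j] <- switch(metric,
      euclidean = sqrt(sum((x - y)^2)),
      jaccard = {
        u <- sum(x == 1 | y == 1)
        if (u == 0) 0 else 1 - sum(x == 1 & y == 1) / u
      },
      hamming = mean(x != y))
  }
  D
}

# Plain Sinkhorn for entropic OT with linear cost only. Unnormalized kernel,
# explicit alternating updates; independent of the package's scaling code.
sinkhorn_oracle <- function(C, p, q, eps, n_iter = 5000) {
  K <- exp(-C / eps)
  u <- rep(1, length(p))
  v <- rep(1, length(q))
  for (i in seq_len(n_iter)) {
    u <- p / as.vector(K %*% v)
    v <- q / as.vector(t(K) %*% u)
  }
  diag(u) %*% K %*% diag(v)
}

# Spearman rho via the Pearson formula on average ranks (manual).
spearman_manual <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Upper-tail probability of a t distribution by numerical integration of the
# density (series-free check of the p-value transform).
t_upper_tail_oracle <- function(t0, df) {
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, lower = t0, upper = Inf, rel.tol = 1e-10)$value
}

# Small hand-built fixtures -------------------------------------------------

# 4-cell map with 3 reference genes; used across I/O and filter tests.
toy_map <- function() {
  spatial_map(
    cell_ids = c("a", "b", "c", "d"),
    coords = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1)),
    ref_genes = c("G1", "G2", "G3"),
    ref_expr = rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 0), c(0, 1, 1))
  )
}

toy_expr <- function(values, genes = colnames(values)) {
  expression_matrix(values, genes = genes)
}

# A small but non-trivial synthetic scene shared by slower tests; cached per
# session so repeated calls are free.
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- make_meristem_map(n_cells = 120, n_ref_genes = 6, seed = 7)
      sim <- simulate_nuclei(gen$map, gen$truth, n_nuclei = 300,
                             n_probe_genes = 20, seed = 7)
      res <- reconstruct_atlas(sim$expr, gen$map, min_prevalence = 3)
      cache <<- list(gen = gen, sim = sim, res = res)
    }
    cache
  }
})
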