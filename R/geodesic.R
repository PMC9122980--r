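#' Geodesic distance matrix on a kNN graph
#'
#' Both sides of the Gromov-Wasserstein problem are represented by the
#' shortest-path structure of a k-nearest-neighbour graph: each row is
#' connected to its `k` nearest rows under the base distance, the directed
#' graph is symmetrized by union, and unweighted shortest-path hop counts
#' are computed. Unreachable pairs (disconnected components) are replaced by
#' (max finite hop count + 1), and the matrix is divided by its maximum so
#' all entries lie in \[0, 1\]. Hop-count geodesics make the representation
#' scale-free: any monotone rescaling of the base distance that preserves
#' neighbour ranks yields the same matrix.
#'
#' @param X numeric matrix; rows are points (3D coordinates for the spatial
#'   map) or expression profiles (for nuclei).
#' @param k number of nearest neighbours (1 <= k < nrow(X)).
#' @param config base distance: a [distance_config()]; the default Euclidean
#'   is used for coordinates.
#' @return an object of class `geodesic_matrix` with fields `D` (square,
#'   symmetric, zero diagonal, entries in \[0,1\]), `k`, and `disconnected`
#'   (TRUE when the kNN graph had more than one component).
#' @export
geodesic_distances <- function(X, k, config = distance_config("euclidean")) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows to build a kNN graph")
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop("k must be smaller than the number of rows")
  base <- if (config$metric == "euclidean") {
    as.matrix(stats::dist(X))
  } else {
    pairwise_distance(X, X, config)
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(base[i, ], seq_len(n))   # ties broken by row index
    ord <- ord[ord != i]
    adj[i, ord[seq_len(k)]] <- TRUE
  }
  adj <- adj | t(adj)                     # union symmetrization
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  hops <- igraph::distances(g)
  disconnected <- any(is.infinite(hops))
  if (disconnected) {
    fill <- max(hops[is.finite(hops)]) + 1
    hops[is.infinite(hops)] <- fill
  }
  D <- hops / max(hops)
  dimnames(D) <- list(rownames(X), rownames(X))
  structure(list(D = D, k = as.integer(k), disconnected = disconnected),
            class = "geodesic_matrix")
}

#' @export
print.geodesic_matrix <- function(x, ...) {
  cat("geodesic_matrix: ", nrow(x$D), " nodes, k = ", x$k,
      if (x$disconnected) ", disconnected components filled", "\n", sep = "")
  invisible(x)
}
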