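#' Distance configuration for transcriptome comparison
#'
#' The linear cost between single-nucleus transcriptomes and the binary
#' spatial-map profiles can use the Euclidean distance or one of two
#' distances for binary data, Jaccard and Hamming. Jaccard/Hamming require
#' binarized single-cell input, so `binarize_sc` is forced on for them;
#' for Euclidean it is optional.
#'
#' @param metric one of `"euclidean"`, `"jaccard"`, `"hamming"`.
#' @param binarize_sc binarize the single-cell side before computing
#'   distances? Ignored (forced TRUE) for jaccard/hamming.
#' @return an object of class `distance_config`.
#' @export
distance_config <- function(metric = c("euclidean", "jaccard", "hamming"),
                            binarize_sc = NULL) {
  metric <- match.arg(metric)
  if (metric %in% c("jaccard", "hamming")) {
    binarize_sc <- TRUE
  } else if (is.null(binarize_sc)) {
    binarize_sc <- FALSE
  }
  structure(list(metric = metric, binarize_sc = isTRUE(binarize_sc)),
            class = "distance_config")
}

#' Pairwise distances between two sets of profiles
#'
#' Rows of `A` are compared against rows of `B`, which must share column
#' order (the same gene set). Jaccard distance is 1 - |intersection|/|union|
#' of the supports (0 when both supports are empty); Hamming distance is the
#' fraction of positions that differ; Euclidean is the l2 norm of the
#' difference. Jaccard and Hamming require binary inputs.
#'
#' @param A,B numeric matrices with identical column counts (and names, when
#'   both are named).
#' @param config a `distance_config`.
#' @return |A| x |B| distance matrix.
#' @export
pairwise_distance <- function(A, B, config = distance_config("euclidean")) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("column mismatch: profiles have different gene counts")
  if (!is.null(colnames(A)) && !is.null(colnames(B)) &&
      !identical(colnames(A), colnames(B)))
    stop("column mismatch: profiles have different gene order")
  metric <- config$metric
  if (metric %in% c("jaccard", "hamming")) {
    if (!all(A %in% c(0, 1)) || !all(B %in% c(0, 1)))
      stop(metric, " distance requires binary inputs (binarize first)")
  }
  D <- switch(metric,
    euclidean = {
      sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      sqrt(pmax(sq, 0))
    },
    jaccard = {
      inter <- tcrossprod(A, B)
      union <- outer(rowSums(A), rowSums(B), "+") - inter
      d <- 1 - inter / union
      d[union == 0] <- 0  # two empty supports: identical, distance 0
      d
    },
    hamming = {
      (tcrossprod(A, 1 - B) + tcrossprod(1 - A, B)) / ncol(A)
    })
  dimnames(D) <- list(rownames(A), rownames(B))
  D
}
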