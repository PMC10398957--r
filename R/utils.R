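#' @importFrom methods as is
#' @importFrom stats rnorm rbeta rnbinom rbinom runif rlnorm pnorm pchisq pt
#'   prcomp cor var sd median p.adjust phyper dhyper setNames aggregate
#'   complete.cases model.matrix
#' @importFrom utils read.delim write.table combn head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

#' Principal-component scores
#'
#' Centered (unscaled) PCA scores of a nuclei x genes matrix, used as the
#' low-dimensional space for neighbor search throughout the pipeline.
#'
#' @param x numeric matrix (dense or sparse), rows = nuclei.
#' @param n_pcs number of components; capped at `min(dim(x)) - 1`.
#' @return numeric matrix of scores, rows aligned with `x`.
#' @export
pca_scores <- function(x, n_pcs = 30L) {
  x <- as.matrix(x)
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  if (n_pcs < 1L) stop("matrix too small for PCA", call. = FALSE)
  sc <- prcomp(x, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
  rownames(sc) <- rownames(x)
  sc
}

#' Exact k-nearest-neighbor search
#'
#' Brute-force Euclidean kNN, block-wise to bound memory. Self matches are
#' excluded.
#'
#' @param x numeric matrix, rows = points.
#' @param k number of neighbors, `1 <= k < nrow(x)`.
#' @param block_size rows per distance block.
#' @return list with `index` (n x k integer) and `dist` (n x k numeric),
#'   neighbors sorted by increasing distance.
#' @export
knn_search <- function(x, k, block_size = 1024L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1L) stop("k must be positive", call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of rows", call. = FALSE)
  xn <- rowSums(x^2)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (start in seq(1L, n, by = block_size)) {
    rows <- start:min(start + block_size - 1L, n)
    d2 <- outer(xn[rows], xn, "+") - 2 * tcrossprod(x[rows, , drop = FALSE], x)
    d2[cbind(seq_along(rows), rows)] <- Inf
    for (j in seq_along(rows)) {
      o <- order(d2[j, ])[seq_len(k)]
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(pmax(d2[j, o], 0))
    }
  }
  list(index = idx, dist = dst)
}

# Sparse row-averaging operator over self + given neighbor indices.
neighbor_mean_operator <- function(index) {
  n <- nrow(index)
  k <- ncol(index)
  i <- rep(seq_len(n), k + 1L)
  j <- c(seq_len(n), as.integer(index))
  Matrix::sparseMatrix(i = i, j = j, x = 1 / (k + 1), dims = c(n, n))
}

as_dense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else as.matrix(x)
}
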