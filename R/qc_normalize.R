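# Gene/nucleus filtering, library-size normalization with natural-log
# transform, and an optional PCA-kNN smoother that plays the role of the
# denoised expression the downstream trajectory analyses assume.

as_sparse_counts <- function(counts) {
  dn <- dimnames(counts)
  m <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (is.null(dimnames(m)) && !is.null(dn)) dimnames(m) <- dn
  if (nrow(m) > 0 && ncol(m) > 0 &&
      (is.null(rownames(m)) || is.null(colnames(m)))) {
    stop("count matrix needs nucleus (row) and gene (column) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicate nucleus or gene identifiers", call. = FALSE)
  }
  m
}

#' Drop genes detected in too few nuclei
#'
#' Retains genes with a nonzero count in at least `min_nuclei` nuclei
#' (default 30), preserving gene order. This removes lowly expressed genes
#' that mostly add statistical noise.
#'
#' @param counts nuclei x genes count matrix (coerced to sparse).
#' @param min_nuclei minimum number of nuclei a gene must be detected in.
#' @return filtered sparse count matrix.
#' @export
filter_genes_min_nuclei <- function(counts, min_nuclei = 30L) {
  if (min_nuclei < 0) stop("min_nuclei must be >= 0", call. = FALSE)
  m <- as_sparse_counts(counts)
  detected <- Matrix::colSums(m > 0)
  m[, detected >= min_nuclei, drop = FALSE]
}

#' Drop nuclei expressing too many genes
#'
#' Retains nuclei whose number of expressed genes is below `max_genes`
#' (default 2500, strict bound); nuclei expressing unusually many genes are
#' likely doublets. Both the bound and its direction are configurable
#' because doublet load varies across datasets.
#'
#' @param counts nuclei x genes count matrix.
#' @param max_genes gene-count bound per nucleus.
#' @param inclusive if `TRUE`, keep nuclei with expressed genes `<= max_genes`
#'   instead of strictly fewer.
#' @return filtered sparse count matrix.
#' @export
filter_nuclei_gene_count <- function(counts, max_genes = 2500L, inclusive = FALSE) {
  if (max_genes <= 0) stop("max_genes must be positive", call. = FALSE)
  m <- as_sparse_counts(counts)
  if (nrow(m) == 0) return(m)
  n_expressed <- Matrix::rowSums(m > 0)
  keep <- if (inclusive) n_expressed <= max_genes else n_expressed < max_genes
  m[keep, , drop = FALSE]
}

#' Library-size normalization and natural-log transform
#'
#' Scales every nucleus to `target_sum` total counts, then applies
#' `x -> ln(1 + x)`. Zero counts map to zero, so sparsity is preserved.
#'
#' @param counts nuclei x genes count matrix.
#' @param target_sum per-nucleus total after scaling; default is the median
#'   pre-normalization depth.
#' @return sparse expression matrix with attributes `normalized`, `logged`,
#'   `smoothed`, `target_sum`.
#' @export
normalize_log <- function(counts, target_sum = NULL) {
  m <- as_sparse_counts(counts)
  depth <- Matrix::rowSums(m)
  zero <- which(depth == 0)
  if (length(zero) > 0) {
    stop("nuclei with zero total counts: ",
         paste(head(rownames(m)[zero], 5), collapse = ", "), call. = FALSE)
  }
  target_sum <- target_sum %||% median(depth)
  if (target_sum <= 0) stop("target_sum must be positive", call. = FALSE)
  scaled <- Matrix::Diagonal(x = target_sum / depth) %*% m
  scaled <- as(scaled, "CsparseMatrix")
  scaled@x <- log1p(scaled@x)
  dimnames(scaled) <- dimnames(m)
  attr(scaled, "normalized") <- TRUE
  attr(scaled, "logged") <- TRUE
  attr(scaled, "smoothed") <- FALSE
  attr(scaled, "target_sum") <- target_sum
  scaled
}

#' Neighborhood smoothing of expression
#'
#' Replaces every nucleus's expression vector by the mean of itself and its
#' `k` nearest neighbors in top-`n_pcs` principal-component space. This is a
#' deterministic, desk-scale denoiser: it plays the role that iterative
#' model-based denoising plays in the original workflow, trading some local
#' bias for a large variance reduction that the per-gene trajectory
#' regressions rely on. `k = 0` is the identity.
#'
#' @param expr nuclei x genes expression matrix (normalized log scale).
#' @param k neighbors to average over (`0 <= k < n_nuclei`).
#' @param n_pcs principal components for the neighbor search.
#' @return dense smoothed matrix with the same dimnames; attribute
#'   `smoothed = TRUE`.
#' @export
knn_smooth <- function(expr, k = 30L, n_pcs = 30L) {
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (k == 0) return(expr)
  n <- nrow(expr)
  if (k >= n) stop("k must be smaller than the number of nuclei", call. = FALSE)
  pcs <- pca_scores(expr, n_pcs)
  nn <- knn_search(pcs, k)
  s <- neighbor_mean_operator(nn$index)
  out <- as.matrix(s %*% expr)
  dimnames(out) <- dimnames(expr)
  attr(out, "normalized") <- attr(expr, "normalized") %||% NA
  attr(out, "logged") <- attr(expr, "logged") %||% NA
  attr(out, "smoothed") <- TRUE
  out
}
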