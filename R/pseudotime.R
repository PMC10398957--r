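# Diffusion-map construction on an adaptive Gaussian kNN kernel, root
# selection at the homeostatic extreme, and diffusion pseudotime (distance
# in scaled eigenvector space from the root) normalized to [0, 1].

#' Diffusion map of an expression matrix or neighbor graph
#'
#' Builds a Gaussian kernel on kNN distances with per-node adaptive
#' bandwidth (distance to the `ceiling(k/2)`-th neighbor), symmetrizes over
#' the kNN union, forms the row-stochastic transition matrix and returns its
#' top nontrivial eigenpairs. Eigenvectors are scaled so they are
#' orthonormal under the stationary measure.
#'
#' @param x nuclei x genes expression matrix, or a `neighbor_graph` from
#'   [build_knn_graph()].
#' @param n_comps nontrivial components to keep.
#' @param k neighbors for the kernel (ignored when `x` is a graph).
#' @param n_pcs principal components for the neighbor search.
#' @param connect bridge disconnected kNN components by their nearest
#'   inter-component pair (possible only when `x` is an expression matrix);
#'   by default disconnection is an error.
#' @return `diffusion_map`: list with `evals` (descending, trivial 1
#'   dropped), `evecs` (nuclei x n_comps), `kernel` (sparse symmetric W),
#'   `degree`, `ids`, `k`, `n_comps`.
#' @export
diffusion_map <- function(x, n_comps = 15L, k = 30L, n_pcs = 30L,
                          connect = FALSE) {
  pcs <- NULL
  if (inherits(x, "neighbor_graph")) {
    dist_m <- x$dist
    k <- x$k
    ids <- x$ids
    n <- length(ids)
    pcs <- x$pcs
  } else {
    n <- nrow(x)
    if (k >= n) stop("k must be smaller than the number of nuclei", call. = FALSE)
    graph <- build_knn_graph(x, n_pcs = n_pcs, k = k)
    dist_m <- graph$dist
    ids <- graph$ids
    pcs <- graph$pcs
  }
  # adaptive bandwidth: distance to the (k/2)-th neighbor
  kk <- max(1L, ceiling(k / 2))
  tri <- Matrix::summary(dist_m)
  sigma <- rep(1, n)
  by_row <- split(tri$x, tri$i)
  for (nm in names(by_row)) {
    d <- sort(by_row[[nm]][by_row[[nm]] > 0])
    if (length(d) > 0) sigma[as.integer(nm)] <- d[min(kk, length(d))]
  }
  sigma[sigma <= 0] <- min(c(sigma[sigma > 0], 1))
  w <- exp(-tri$x^2 / (sigma[tri$i] * sigma[tri$j]))
  kernel <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = w, dims = c(n, n)) +
    Matrix::Diagonal(n)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    kernel, mode = "max", weighted = TRUE, diag = FALSE))
  if (comp$no > 1) {
    if (!connect || is.null(pcs)) {
      stop("neighbor graph is disconnected (", comp$no,
           " components); subset to the largest connected component first",
           call. = FALSE)
    }
    kernel <- bridge_components(kernel, comp$membership, pcs, sigma)
  }
  deg <- Matrix::rowSums(kernel)
  dhalf <- 1 / sqrt(deg)
  a <- Matrix::Diagonal(x = dhalf) %*% kernel %*% Matrix::Diagonal(x = dhalf)
  eig <- eigen(as.matrix(Matrix::forceSymmetric(a)), symmetric = TRUE)
  n_comps <- min(n_comps, n - 1L)
  evals <- eig$values[2:(n_comps + 1L)]
  psi <- eig$vectors[, 2:(n_comps + 1L), drop = FALSE] * dhalf
  # normalize so psi' D psi = I (v orthonormal => psi = D^{-1/2} v already is,
  # up to the measure scaling); fix sign convention: largest-|.| entry positive
  for (j in seq_len(ncol(psi))) {
    if (psi[which.max(abs(psi[, j])), j] < 0) psi[, j] <- -psi[, j]
  }
  rownames(psi) <- ids
  structure(list(evals = evals, evecs = psi, kernel = kernel, degree = deg,
                 ids = ids, k = k, n_comps = n_comps),
            class = "diffusion_map")
}

# Connect every smaller kNN component to the largest one through its
# nearest inter-component pair in PC space, with a kernel weight from the
# same adaptive-bandwidth formula.
bridge_components <- function(kernel, membership, pcs, sigma) {
  main <- which.max(tabulate(membership))
  anchor <- which(membership == main)
  for (cmp in setdiff(unique(membership), main)) {
    members <- which(membership == cmp)
    d2 <- outer(rowSums(pcs[members, , drop = FALSE]^2),
                rowSums(pcs[anchor, , drop = FALSE]^2), "+") -
      2 * tcrossprod(pcs[members, , drop = FALSE], pcs[anchor, , drop = FALSE])
    best <- arrayInd(which.min(d2), dim(d2))
    i <- members[best[1]]
    j <- anchor[best[2]]
    # bandwidth floored at the bridge distance so the weight cannot
    # underflow: diffusion across the bridge is slow but nonzero
    d2b <- max(d2[best], 0)
    w <- exp(-d2b / max(sigma[i] * sigma[j], d2b))
    kernel[i, j] <- kernel[j, i] <- max(kernel[i, j], w)
    anchor <- c(anchor, members)
  }
  kernel
}

#' Transition matrix of a diffusion map
#'
#' Row-stochastic transition matrix `P = D^-1 W` of the kernel.
#'
#' @param dmap a `diffusion_map`.
#' @return sparse row-stochastic matrix.
#' @export
transition_matrix <- function(dmap) {
  Matrix::Diagonal(x = 1 / dmap$degree) %*% dmap$kernel
}

#' Select the root nucleus
#'
#' The root is the candidate minimizing a layout axis (by default the first
#' nontrivial diffusion component, sign-fixed so the homeostatic-high end is
#' negative). Ties are broken by the highest homeostatic panel score, then
#' by the lexicographically smallest nucleus ID.
#'
#' @param axis named numeric vector of axis values per nucleus.
#' @param candidates nucleus IDs eligible as root (e.g. the protoplasmic
#'   cluster).
#' @param homeostatic_score optional named score vector for tie-breaking.
#' @return the root nucleus ID.
#' @export
select_root <- function(axis, candidates = names(axis), homeostatic_score = NULL) {
  if (length(candidates) == 0) stop("candidate set is empty", call. = FALSE)
  if (is.null(names(axis))) names(axis) <- as.character(seq_along(axis))
  candidates <- as.character(candidates)
  missing <- setdiff(candidates, names(axis))
  if (length(missing) > 0) stop("candidates missing from axis", call. = FALSE)
  vals <- axis[candidates]
  tied <- candidates[vals <= min(vals) + 1e-12]
  if (length(tied) > 1 && !is.null(homeostatic_score)) {
    sc <- homeostatic_score[tied]
    tied <- tied[sc >= max(sc) - 1e-12]
  }
  sort(tied)[1]
}

#' Diffusion pseudotime from a root nucleus
#'
#' `t(x)` is the Euclidean distance between the scaled diffusion
#' representations `psi_i * lambda_i / (1 - lambda_i)` of `x` and the root,
#' divided by its maximum so `t` spans \[0, 1\] with `t(root) = 0`.
#'
#' @param dmap a `diffusion_map`.
#' @param root nucleus ID (or index) of the root.
#' @return `pseudotime_result` data.frame: nucleus_id, t, is_root; attribute
#'   `root`.
#' @export
diffusion_pseudotime <- function(dmap, root) {
  if (any(dmap$evals >= 1 - 1e-10)) {
    stop("nontrivial eigenvalue equals 1: graph is disconnected", call. = FALSE)
  }
  if (is.character(root)) {
    root_idx <- match(root, dmap$ids)
    if (is.na(root_idx)) stop("root nucleus not in the map", call. = FALSE)
  } else {
    root_idx <- as.integer(root)
    if (root_idx < 1 || root_idx > length(dmap$ids)) {
      stop("root nucleus not in the map", call. = FALSE)
    }
  }
  scale <- dmap$evals / (1 - dmap$evals)
  rep_m <- sweep(dmap$evecs, 2, scale, "*")
  delta <- sweep(rep_m, 2, rep_m[root_idx, ], "-")
  t <- sqrt(rowSums(delta^2))
  if (length(t) > 1 && max(t) > 0) t <- t / max(t)
  out <- data.frame(nucleus_id = dmap$ids, t = t,
                    is_root = seq_along(t) == root_idx,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "root") <- dmap$ids[root_idx]
  class(out) <- c("pseudotime_result", "data.frame")
  out
}

#' Full pseudotime computation with the homeostatic root rule
#'
#' Convenience wrapper: diffusion map, root axis = first nontrivial
#' component oriented so the homeostatic-panel-high end is negative, root =
#' axis minimum among `candidates`, then diffusion pseudotime.
#'
#' @param expr nuclei x genes expression matrix for the analysis
#'   populations.
#' @param homeo_genes homeostatic panel used to orient the axis and break
#'   root ties.
#' @param candidates nucleus IDs eligible as root (default all).
#' @param k,n_pcs,n_comps diffusion-map parameters.
#' @param connect bridge disconnected components (see [diffusion_map()]);
#'   on by default here because the joint astrocyte populations can form
#'   separated clusters that still share one trajectory analysis.
#' @return `pseudotime_result` with attributes `root` and `dmap`.
#' @export
compute_pseudotime <- function(expr, homeo_genes, candidates = NULL,
                               k = 30L, n_pcs = 30L, n_comps = 15L,
                               connect = TRUE) {
  dmap <- diffusion_map(expr, n_comps = n_comps, k = k, n_pcs = n_pcs,
                        connect = connect)
  genes <- intersect(homeo_genes, colnames(expr))
  if (length(genes) == 0) stop("no homeostatic panel genes in matrix", call. = FALSE)
  score <- rowMeans(as_dense(expr[, genes, drop = FALSE]))
  names(score) <- rownames(expr)
  axis <- dmap$evecs[, 1]
  names(axis) <- dmap$ids
  if (cor(axis, score) > 0) axis <- -axis
  root <- select_root(axis, candidates %||% dmap$ids, score)
  res <- diffusion_pseudotime(dmap, root)
  attr(res, "dmap") <- dmap
  res
}
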