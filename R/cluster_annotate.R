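# Neighbor-graph construction, Leiden clustering across resolutions,
# cluster-vs-rest Wilcoxon marker detection, marker-panel annotation with
# doublet flagging, and the cluster-flow (Sankey) table.

#' Build a kNN neighbor graph in PC space
#'
#' Euclidean kNN in top-`n_pcs` principal-component space, symmetrized by
#' taking the union of directed edges (max symmetrization), no self loops.
#'
#' @param expr nuclei x genes expression matrix.
#' @param n_pcs principal components.
#' @param k neighbors per nucleus (`0 < k < n_nuclei`).
#' @return `neighbor_graph`: list with sparse symmetric `adjacency` (0/1
#'   weights), `dist` (sparse symmetric distances), `pcs`, `k`, `n_pcs`,
#'   `ids`.
#' @export
build_knn_graph <- function(expr, n_pcs = 30L, k = 15L) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  n <- nrow(expr)
  if (k >= n) stop("k must be smaller than the number of nuclei", call. = FALSE)
  pcs <- pca_scores(expr, n_pcs)
  nn <- knn_search(pcs, k)
  i <- rep(seq_len(n), k)
  j <- as.integer(nn$index)
  d <- as.numeric(nn$dist)
  # union-symmetrize; drop duplicate (i,j) pairs keeping one value
  ii <- c(i, j); jj <- c(j, i); dd <- c(d, d)
  key <- (ii - 1) * n + jj
  keep <- !duplicated(key)
  adjacency <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep],
                                    x = rep(1, sum(keep)), dims = c(n, n))
  dist_m <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = dd[keep],
                                 dims = c(n, n))
  ids <- rownames(expr) %||% as.character(seq_len(n))
  dimnames(adjacency) <- list(ids, ids)
  dimnames(dist_m) <- list(ids, ids)
  structure(list(adjacency = adjacency, dist = dist_m, pcs = pcs,
                 k = k, n_pcs = ncol(pcs), ids = ids),
            class = "neighbor_graph")
}

graph_to_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Leiden clustering across a resolution sweep
#'
#' Modularity-based Leiden community detection at each requested resolution;
#' deterministic given the seed.
#'
#' @param graph a `neighbor_graph`.
#' @param resolutions numeric vector of resolution parameters.
#' @param seed RNG seed for tie-breaking.
#' @return `cluster_assignments`: data.frame of integer labels, one column
#'   `res_<r>` per resolution, rownames = nucleus IDs; attribute
#'   `resolutions`.
#' @export
cluster_sweep <- function(graph, resolutions, seed = 1L) {
  if (length(resolutions) == 0) stop("resolution list is empty", call. = FALSE)
  if (nrow(graph$adjacency) == 0) stop("empty graph", call. = FALSE)
  g <- graph_to_igraph(graph)
  cols <- lapply(resolutions, function(res) {
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = res, n_iterations = 3)
    as.integer(igraph::membership(cl))
  })
  out <- as.data.frame(cols, col.names = sprintf("res_%g", resolutions))
  rownames(out) <- graph$ids
  attr(out, "resolutions") <- resolutions
  class(out) <- c("cluster_assignments", "data.frame")
  out
}

# Two-sample Wilcoxon rank-sum test with midranks. Exact enumeration over
# all rank splits when the smaller group has <= `exact_max` members,
# otherwise tie-corrected normal approximation (no continuity correction).
#' Wilcoxon rank-sum test
#'
#' @param x,y numeric vectors.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default enumerates when `min(length(x), length(y)) <= 6`.
#' @return list with `statistic` (rank sum of `x`), `p.value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  exact <- exact %||% (min(n1, n2) <= 6)
  if (exact) {
    splits <- combn(n, n1)
    ws <- colSums(matrix(r[splits], nrow = n1))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    return(list(statistic = w, p.value = p, method = "exact"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(list(statistic = w, p.value = 1, method = "normal"))
  z <- (w - mu) / sqrt(v)
  list(statistic = w, p.value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Cluster-vs-rest Wilcoxon marker table
#'
#' For every cluster and gene, a two-sided rank-sum test of the cluster
#' against all other nuclei, with a natural-log fold change (difference of
#' mean log expression) and Benjamini-Hochberg adjustment within each
#' cluster's gene list.
#'
#' @param expr nuclei x genes expression matrix (normalized log scale).
#' @param labels cluster label per nucleus.
#' @return `marker_table` data.frame: gene, cluster, lfc, statistic, p.value,
#'   q.value.
#' @export
wilcoxon_markers <- function(expr, labels) {
  labels <- as.character(labels)
  expr <- as_dense(expr)
  stopifnot(length(labels) == nrow(expr))
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("need at least two clusters", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < 2)) stop("every cluster needs at least two nuclei", call. = FALSE)
  n <- nrow(expr)
  m <- ncol(expr)
  ranks <- apply(expr, 2, rank)
  # tie correction term per gene
  tie_term <- apply(ranks, 2, function(r) {
    t <- rle(sort(r))$lengths
    sum(t^3 - t)
  })
  gene_means <- colMeans(expr)
  out <- vector("list", length(cls))
  for (ci in seq_along(cls)) {
    members <- labels == cls[ci]
    n1 <- sum(members); n2 <- n - n1
    w <- colSums(ranks[members, , drop = FALSE])
    if (min(n1, n2) <= 6) {
      p <- vapply(seq_len(m), function(g) {
        rank_sum_test(expr[members, g], expr[!members, g])$p.value
      }, numeric(1))
    } else {
      mu <- n1 * (n + 1) / 2
      v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
      z <- ifelse(v > 0, (w - mu) / sqrt(v), 0)
      p <- ifelse(v > 0, pmin(1, 2 * pnorm(-abs(z))), 1)
    }
    in_mean <- colMeans(expr[members, , drop = FALSE])
    lfc <- in_mean - (gene_means * n - in_mean * n1) / n2
    out[[ci]] <- data.frame(gene = colnames(expr) %||% as.character(seq_len(m)),
                            cluster = cls[ci], lfc = lfc, statistic = w,
                            p.value = p, q.value = bh_adjust(p),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Label clusters from marker panels
#'
#' Scores every cluster against each marker panel as the mean log-fold
#' change of the panel's significant markers (BH q below `q_threshold`).
#' Clusters are labeled by their best astrocyte panel, except that a doublet
#' panel (neuron/oligodendrocyte) exceeding the best astrocyte score flags
#' the cluster as a doublet. Clusters with no significant panel gene are
#' `unassigned`.
#'
#' @param markers a `marker_table` from [wilcoxon_markers()].
#' @param panels named list of gene vectors; names `protoplasmic`,
#'   `fibrous`, `neuron`, `oligo` (see [marker_panels()]).
#' @param q_threshold significance cut for panel genes.
#' @return data.frame: cluster, label, and one score column per panel.
#' @export
annotate_clusters <- function(markers, panels, q_threshold = 0.05) {
  if (length(panels) == 0 || any(lengths(panels) == 0)) {
    stop("panels must be non-empty", call. = FALSE)
  }
  cls <- unique(markers$cluster)
  astro <- intersect(c("protoplasmic", "fibrous"), names(panels))
  doubl <- intersect(c("neuron", "oligo"), names(panels))
  doubl_label <- c(neuron = "doublet_neuron", oligo = "doublet_oligo")
  rows <- lapply(cls, function(cl) {
    mk <- markers[markers$cluster == cl & markers$q.value < q_threshold, ]
    scores <- vapply(panels, function(genes) {
      hit <- mk$lfc[mk$gene %in% genes]
      if (length(hit) == 0) -Inf else mean(hit)
    }, numeric(1))
    label <- "unassigned"
    if (any(is.finite(scores))) {
      best_astro <- if (length(astro)) max(scores[astro]) else -Inf
      best_doubl <- if (length(doubl)) max(scores[doubl]) else -Inf
      if (best_doubl > best_astro && is.finite(best_doubl)) {
        label <- doubl_label[[doubl[which.max(scores[doubl])]]]
      } else if (is.finite(best_astro)) {
        label <- astro[which.max(scores[astro])]
      }
    }
    cbind(data.frame(cluster = cl, label = label, stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(scores, paste0("score_", names(panels))))))
  })
  do.call(rbind, rows)
}

#' Cluster flow between adjacent resolutions
#'
#' Edge table for a Sankey view of how clusters split or merge as the
#' clustering resolution increases: one row per (label at resolution i,
#' label at resolution i+1) pair with the number of shared nuclei.
#'
#' @param assignments a `cluster_assignments` table (>= 2 resolutions).
#' @return data.frame: res_from, label_from, res_to, label_to, n.
#' @export
cluster_flow_table <- function(assignments) {
  cols <- colnames(assignments)
  if (length(cols) < 2) stop("need at least two resolutions", call. = FALSE)
  out <- list()
  for (i in seq_len(length(cols) - 1)) {
    tab <- as.data.frame(table(from = assignments[[cols[i]]],
                               to = assignments[[cols[i + 1]]]),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, ]
    out[[i]] <- data.frame(res_from = cols[i], label_from = tab$from,
                           res_to = cols[i + 1], label_to = tab$to,
                           n = tab$Freq, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
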