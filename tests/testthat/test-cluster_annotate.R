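# Neighbor graph, Leiden sweep, Wilcoxon markers, panel annotation,
# cluster-flow table.

test_that("kNN graph symmetrizes by edge union and has no self loops", {
  x <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(c("a", "b", "c"), "d1"))
  g <- build_knn_graph(x, n_pcs = 1, k = 1)
  a <- as.matrix(g$adjacency)
  expect_equal(a, t(a))
  expect_true(all(diag(a) == 0))
  # middle point keeps both incident edges after symmetrization
  expect_equal(unname(a["b", c("a", "c")]), c(1, 1))
  expect_error(build_knn_graph(x, k = 0), "positive")
  expect_error(build_knn_graph(x, k = 3), "smaller")
})

test_that("well-separated blobs give disconnected graph components", {
  blobs <- make_blobs(n_per = 40, centers = 2, dims = 5, sd = 0.3, seed = 2)
  g <- build_knn_graph(blobs$x, n_pcs = 5, k = 4)
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  expect_equal(igraph::components(ig)$no, 2)
})

test_that("cluster_sweep is deterministic and recovers planted populations", {
  blobs <- make_blobs(n_per = 100, centers = 4, dims = 20, sd = 0.6, seed = 3)
  g <- build_knn_graph(blobs$x, n_pcs = 10, k = 10)
  res <- cluster_sweep(g, resolutions = c(0.1, 0.5, 1), seed = 11)
  expect_equal(colnames(res), c("res_0.1", "res_0.5", "res_1"))
  expect_equal(nrow(res), 400)
  res2 <- cluster_sweep(g, resolutions = c(0.1, 0.5, 1), seed = 11)
  expect_identical(res, res2)

  ari <- vapply(res, function(l) mclust::adjustedRandIndex(l, blobs$labels),
                numeric(1))
  expect_gte(max(ari), 0.9)
  expect_error(cluster_sweep(g, numeric(0)), "empty")
})

test_that("rank_sum_test matches enumeration, midranks, and wilcox.test", {
  # fully separated groups: only the two extreme splits are as extreme
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(rank_sum_test(c(7, 7, 7), c(7, 7, 7))$p.value, 1)
  expect_equal(rank_sum_test(c(1, 2), c(1, 2))$p.value, 1)

  set.seed(5)
  for (i in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1), sample(0:1, 1))  # occasional ties
    y <- round(rnorm(n2), 1)
    expect_equal(rank_sum_test(x, y)$p.value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
  # normal-approximation path against the standard implementation
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(12)
    ours <- rank_sum_test(x, y, exact = FALSE)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("wilcoxon_markers tests cluster-vs-rest with BH within cluster", {
  set.seed(6)
  n <- 60
  labels <- rep(c("A", "B", "C"), each = 20)
  expr <- matrix(rnorm(n * 8), n, 8,
                 dimnames = list(sprintf("n%02d", 1:n), sprintf("g%d", 1:8)))
  expr[labels == "A", 1] <- expr[labels == "A", 1] + 3
  mk <- wilcoxon_markers(expr, labels)
  expect_equal(nrow(mk), 3 * 8)
  expect_true(all(mk$q.value >= mk$p.value - 1e-12))
  expect_true(all(mk$q.value <= 1))
  top <- mk[mk$cluster == "A" & mk$gene == "g1", ]
  expect_lt(top$p.value, 1e-6)
  expect_gt(top$lfc, 2)
  # per-gene p agrees with the two-sample test
  g3 <- mk[mk$cluster == "B" & mk$gene == "g3", ]
  expect_equal(g3$p.value,
               rank_sum_test(expr[labels == "B", 3],
                             expr[labels != "B", 3], exact = FALSE)$p.value,
               tolerance = 1e-12)

  expect_error(wilcoxon_markers(expr, rep("A", n)), "two clusters")
  expect_error(wilcoxon_markers(expr, c("B", rep("A", n - 1))), "at least two nuclei")
})

test_that("annotate_clusters labels by panels with doublet precedence", {
  panels <- list(protoplasmic = c("p1", "p2"), fibrous = c("f1", "f2"),
                 neuron = c("n1", "n2"), oligo = c("o1", "o2"))
  mk <- function(cluster, genes, lfc, q = 0.001) {
    data.frame(gene = genes, cluster = cluster, lfc = lfc,
               statistic = 0, p.value = q, q.value = q)
  }
  markers <- rbind(
    mk("c1", c("p1", "p2"), c(2, 1.5)),                    # protoplasmic
    mk("c2", c("p1", "n1", "n2"), c(1, 2.5, 2)),           # neuron > astro
    mk("c3", c("f1"), 0.5, q = 0.9))                       # nothing significant
  ann <- annotate_clusters(markers, panels)
  expect_equal(ann$label[ann$cluster == "c1"], "protoplasmic")
  expect_equal(ann$label[ann$cluster == "c2"], "doublet_neuron")
  expect_equal(ann$label[ann$cluster == "c3"], "unassigned")
  expect_error(annotate_clusters(markers, list()), "non-empty")
})

test_that("cluster_flow_table conserves nuclei between resolutions", {
  asg <- data.frame(res_a = c(1, 1, 1, 1), res_b = c(1, 1, 1, 1))
  flow <- cluster_flow_table(asg)
  expect_equal(nrow(flow), 1)
  expect_equal(flow$n, 4)

  # one cluster splitting in two: two outgoing edges
  asg2 <- data.frame(res_a = c(1, 1, 1, 1, 2, 2),
                     res_b = c(1, 1, 3, 3, 2, 2))
  flow2 <- cluster_flow_table(asg2)
  out1 <- flow2[flow2$label_from == 1, ]
  expect_equal(nrow(out1), 2)
  expect_equal(sum(out1$n), 4)
  expect_equal(sum(flow2$n), 6)
  expect_error(cluster_flow_table(asg2["res_a"]), "two resolutions")
})
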