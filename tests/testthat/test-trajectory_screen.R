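# Rank-uniformization and the per-gene trajectory regression screen.

test_that("rank_uniform spreads values on [0,1] and ignores monotone warping", {
  expect_equal(rank_uniform(c(0.5, 0.1, 0.9)), c(0.5, 0, 1))
  t <- runif(51)
  u <- rank_uniform(t)
  expect_equal(range(u), c(0, 1))
  expect_equal(sort(u), seq(0, 1, length.out = 51))
  expect_equal(rank_uniform(exp(7 * t)), u)      # strictly monotone transform
  expect_equal(rank_uniform(t, scale = "raw"), rank(t))
  # midranks for ties, then rescaled
  expect_equal(rank_uniform(c(1, 1, 2)), c(0.25, 0.25, 1))
  expect_error(rank_uniform(0.3), "two")
})

test_that("gene regression handles exact fits, constants, and errors", {
  t <- seq(0, 1, length.out = 40)
  u <- rank_uniform(t)
  expr <- cbind(perfect = u, constant = rep(2, 40), noise = rnorm(40))
  rownames(expr) <- sprintf("n%02d", 1:40)
  rec <- gene_trajectory_regression(expr, u)
  p <- rec[rec$gene == "perfect", ]
  expect_equal(p$beta, 1, tolerance = 1e-12)
  expect_equal(p$r2, 1, tolerance = 1e-12)
  k <- rec[rec$gene == "constant", ]
  expect_equal(k$beta, 0)
  expect_equal(k$r2, 0)
  expect_equal(k$p_raw, 1)
  expect_equal(rec$mean_expr[2], 2)
  expect_true(all(rec$p_bonf >= rec$p_raw))
  expect_error(gene_trajectory_regression(expr, rep(0.5, 40)), "zero variance")
})

test_that("regression equals closed-form least squares from lm()", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 50; m <- 20
    expr <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, sprintf("g%02d", 1:m)))
    u <- rank_uniform(runif(n))
    rec <- gene_trajectory_regression(expr, u)
    for (j in seq_len(m)) {
      fit <- summary(lm(expr[, j] ~ u))
      expect_equal(rec$beta[j], unname(fit$coefficients["u", "Estimate"]),
                   tolerance = 1e-10)
      expect_equal(rec$r2[j], fit$r.squared, tolerance = 1e-10)
      expect_equal(rec$p_raw[j], unname(fit$coefficients["u", "Pr(>|t|)"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("planted slope is recovered without bias over repeated draws", {
  betas <- vapply(1:20, function(seed) {
    set.seed(seed)
    t <- runif(2000)
    y <- cbind(g = 0.3 * t + rnorm(2000, sd = 0.3))
    gene_trajectory_regression(y, rank_uniform(t))$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.3), 0.05)
})

test_that("classification applies the two-sided effect/variance/significance rule", {
  rec <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    beta = c(0.12, -0.2, 0.05, 0.3, -0.15),
                    r2 = c(0.15, 0.3, 0.5, 0.05, 0.2),
                    p_raw = 1e-6, p_bonf = c(0.01, 1e-5, 1e-9, 1e-4, 0.2),
                    mean_expr = 1)
  out <- classify_dysregulated(rec)
  expect_equal(out$up, "a")              # passes all three thresholds
  expect_equal(out$down, "b")
  st <- out$records$status
  expect_equal(st, c("up", "down", "ns", "ns", "ns"))
  # c fails beta_min despite tiny p; d fails r2_min; e fails alpha
})

test_that("MA table drops exclusions and non-significant genes", {
  rec <- data.frame(gene = c("MALAT1", "g1", "g2"),
                    beta = c(0.5, 0.2, 0.1), r2 = c(0.4, 0.3, 0.2),
                    p_raw = c(1e-9, 1e-9, 0.5), p_bonf = c(1e-6, 1e-6, 1),
                    mean_expr = c(8, 2, 1),
                    status = c("up", "up", "ns"))
  ma <- ma_table(rec)
  expect_equal(ma$gene, "g1")
  expect_named(ma, c("gene", "mean_expr", "beta", "r2", "status"))
  # without exclusions and with everything significant, all rows survive
  rec2 <- rec[rec$gene != "MALAT1", ]
  rec2$p_bonf <- 1e-6
  ma2 <- ma_table(rec2, screen_config(plot_exclusions = character(0)))
  expect_equal(nrow(ma2), nrow(rec2))
})

test_that("the identical screen on the microglia preset is up-dominated", {
  cfg <- simulation_config_microglia(n_nuclei = 900L, seed = 17L)
  ds <- simulate_dataset(cfg)
  e <- normalize_log(ds$counts)
  es <- knn_smooth(e, k = 30, n_pcs = 10)
  pt <- compute_pseudotime(knn_smooth(e, k = 30, n_pcs = 30),
                           homeo_genes = c("NRXN1", "NRG3", "GPC5", "ERBB4",
                                           "NFIA"))
  rec <- gene_trajectory_regression(es[match(pt$nucleus_id, rownames(es)), ],
                                    rank_uniform(pt$t))
  ma <- ma_table(rec)
  expect_gt(sum(ma$status == "up"), sum(ma$status == "down"))
  expect_false("MALAT1" %in% ma$gene)
})
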