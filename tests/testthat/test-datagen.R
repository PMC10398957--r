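# Synthetic cohort generator: determinism, ground truth, doublets,
# planted-effect structure.

test_that("config validation names the offending field", {
  expect_error(simulation_config(apoe_freq = c("E3/E3" = 0.5, "E3/E4" = 0.2,
                                               "E4/E4" = 0.2)),
               "apoe_freq")
  expect_error(simulation_config(n_genes = 100L), "n_genes")
  expect_error(simulation_config(amyloid_positive = 99L), "amyloid_positive")
  expect_error(simulation_config(nuclei_per_type = c(protoplasmic = 10L)),
               "nuclei_per_type")
  expect_error(simulation_config(depth_mean = 0), "depth_mean")
})

test_that("identical config and seed give identical datasets and MTX files", {
  cfg <- small_sim_config(seed = 5L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(d1$counts), as.matrix(d2$counts))
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$meta, d2$meta)

  dir1 <- tempfile(); dir2 <- tempfile()
  write_dataset(d1, dir1)
  write_dataset(d2, dir2)
  expect_identical(unname(tools::md5sum(file.path(dir1, "matrix.mtx"))),
                   unname(tools::md5sum(file.path(dir2, "matrix.mtx"))))

  back <- read_count_matrix(dir1)
  expect_equal(as.matrix(back), as.matrix(d1$counts))
  expect_equal(read_nucleus_meta(dir1)$nucleus_id, d1$meta$nucleus_id)
})

test_that("ground truth carries the planted program sizes and alignment", {
  cfg <- simulation_config(nuclei_per_type = c(protoplasmic = 60L, fibrous = 30L,
                                               doublet_neuron = 10L,
                                               doublet_oligo = 10L),
                           seed = 2L)
  ds <- simulate_dataset(cfg)
  sig <- truth_signature(ds)
  expect_length(sig$up, 52)
  expect_length(sig$down, 144)
  g <- ds$truth$genes
  expect_length(intersect(c(sig$up, sig$down), g$gene[g$direction == "null"]), 0)
  expect_equal(nrow(ds$counts), nrow(ds$meta))
  expect_equal(nrow(ds$counts), nrow(ds$truth$nuclei))
  expect_true(all(ds$counts@x >= 0 & ds$counts@x == round(ds$counts@x)))
  # reactivity defined exactly for protoplasmic nuclei
  tn <- ds$truth$nuclei
  expect_true(all(!is.na(tn$r[tn$population == "protoplasmic"])))
  expect_true(all(is.na(tn$r[tn$population != "protoplasmic"])))
  expect_true(all(tn$r >= 0 & tn$r <= 1, na.rm = TRUE))
  # doublets have exactly two parents
  dbl <- tn[grepl("doublet", tn$population), ]
  expect_true(all(!is.na(dbl$parent_a) & !is.na(dbl$parent_b)))

  empty_up <- simulate_dataset(small_sim_config(seed = 1L, n_up = 0L))
  expect_length(truth_signature(empty_up)$up, 0)
})

test_that("make_doublets sums parents, thins to depth, and validates n", {
  counts <- rbind(a = c(1, 0, 2), b = c(0, 3, 0))
  colnames(counts) <- c("g1", "g2", "g3")
  labels <- c("A", "B")
  res <- make_doublets(counts, labels, c("A", "B"), 1)
  expect_equal(unname(res$counts[1, ]), c(1, 3, 2))

  res0 <- make_doublets(counts, labels, c("A", "B"), 0)
  expect_equal(nrow(res0$counts), 0)

  expect_error(make_doublets(counts, labels, c("A", "B"), 2), "parent pairs")
  expect_error(make_doublets(counts, c("A", "A"), c("A", "B"), 1), "present")

  set.seed(4)
  big <- matrix(rpois(40 * 50, 5), 40, 50)
  lab <- rep(c("A", "B"), each = 20)
  thin <- make_doublets(big, lab, c("A", "B"), 10, target_depth = 100)
  expect_true(all(rowSums(thin$counts) <= 100 + 30))  # binomial, so near target
  # conservation without thinning: doublet totals equal summed parents
  keep <- make_doublets(big, lab, c("A", "B"), 10)
  expect_equal(rowSums(keep$counts),
               rowSums(big[keep$parent_a, ]) + rowSums(big[keep$parent_b, ]))
})

test_that("astrocyte-neuron doublets score high on the neuron marker panel", {
  cfg <- simulation_config(nuclei_per_type = c(protoplasmic = 200L, fibrous = 0L,
                                               doublet_neuron = 60L,
                                               doublet_oligo = 0L),
                           n_genes = 600L, n_weak = 0L, seed = 3L)
  ds <- simulate_dataset(cfg)
  e <- as.matrix(normalize_log(ds$counts))
  score <- rowMeans(e[, marker_panels()$neuron])
  pop <- ds$truth$nuclei$population
  singlet_q90 <- quantile(score[pop == "protoplasmic"], 0.9)
  expect_true(all(score[pop == "doublet_neuron"] > singlet_q90))
})

test_that("planted slopes leave a sign-consistent trace in expression", {
  cfg <- simulation_config(nuclei_per_type = c(protoplasmic = 1000L, fibrous = 0L,
                                               doublet_neuron = 0L,
                                               doublet_oligo = 0L),
                           n_genes = 500L, n_weak = 0L, seed = 6L)
  ds <- simulate_dataset(cfg)
  e <- as.matrix(normalize_log(ds$counts))
  r <- ds$truth$nuclei$r
  g <- ds$truth$genes
  up <- utils::head(g$gene[g$direction == "up"], 10)
  down <- utils::head(g$gene[g$direction == "down"], 10)
  expect_true(all(cor(e[, up], r) > 0))
  expect_true(all(cor(e[, down], r) < 0))
})

test_that("no planted effect means no planted signal", {
  cfg <- simulation_config(nuclei_per_type = c(protoplasmic = 400L, fibrous = 0L,
                                               doublet_neuron = 0L,
                                               doublet_oligo = 0L),
                           n_genes = 500L, n_weak = 0L,
                           slope_up = 0, slope_down = 0, amyloid_shift = 0,
                           seed = 8L)
  ds <- simulate_dataset(cfg)
  e <- normalize_log(ds$counts)
  r <- ds$truth$nuclei$r
  rec <- gene_trajectory_regression(e, rank_uniform(r))
  # planted and null genes indistinguishable: raw p roughly uniform
  g <- ds$truth$genes
  p_planted <- rec$p_raw[rec$gene %in% g$gene[g$direction %in% c("up", "down")]]
  expect_gt(mean(p_planted < 0.05) , 0)   # not degenerate
  expect_lt(mean(p_planted < 0.05), 0.15) # ~alpha false positives
  expect_equal(sum(rec$status != "ns"), 0)
})

test_that("draw_reactivity reflects the planted amyloid shift at the donor level", {
  cfg <- simulation_config(seed = 10L)
  rr <- draw_reactivity(cfg, nuclei_per_donor = 400L)
  expect_true(all(rr$r >= 0 & rr$r <= 1))
  gap <- mean(rr$r[rr$amyloid == 1]) - mean(rr$r[rr$amyloid == 0])
  expect_gt(gap, 0.02)
  expect_lt(gap, 0.25)
})

test_that("the microglia preset plants an up-dominated program", {
  cfg <- simulation_config_microglia(n_nuclei = 100L, seed = 1L)
  ds <- simulate_dataset(cfg)
  g <- ds$truth$genes
  expect_equal(sum(g$direction == "up"), 200)
  expect_equal(sum(g$direction == "down"), 30)
  expect_true(all(g$slope[g$direction == "up"] == 0.4))
})
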