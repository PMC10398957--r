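# Exact-test primitives and the cross-signature enrichment operations.

test_that("fisher_exact_2x2 matches hand-checked values", {
  res <- fisher_exact_2x2(c(1, 1, 1, 1))
  expect_equal(res$p.value, 1)
  expect_equal(res$odds.ratio, 1)

  # all mass on the diagonal: only the observed and mirrored tables are as
  # extreme, each with probability 1/C(10,5)
  res <- fisher_exact_2x2(c(5, 0, 0, 5))
  expect_equal(res$p.value, 2 / 252)
  expect_identical(res$odds.ratio, Inf)

  res <- fisher_exact_2x2(c(0, 5, 5, 0))
  expect_equal(res$p.value, 2 / 252)
  expect_equal(res$odds.ratio, 0)

  # mouse-model overlap counts: strong enrichment
  res <- fisher_exact_2x2(c(29, 195, 167, 16621))
  expect_lt(res$p.value, 1e-4)
  expect_gt(res$odds.ratio, 10)
})

test_that("fisher_exact_2x2 agrees with enumeration and stats::fisher.test", {
  set.seed(42)
  for (i in 1:200) {
    tab <- as.vector(stats::rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
    ours <- fisher_exact_2x2(tab)
    expect_equal(ours$p.value, oracle_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))
    expect_equal(ours$p.value, ft$p.value, tolerance = 1e-7)
  }
})

test_that("fisher_exact_2x2 rejects invalid tables", {
  expect_error(fisher_exact_2x2(c(-1, 1, 1, 1)), "non-negative")
  expect_error(fisher_exact_2x2(c(1, 1, 1)), "four cells")
  expect_error(fisher_exact_2x2(c(0, 0, 0, 0)), "positive")
  expect_error(fisher_exact_2x2(c(0.5, 1, 1, 1)), "integer")
})

test_that("chi_squared_2x2 matches the closed form and stats::chisq.test", {
  res <- chi_squared_2x2(c(10, 10, 10, 10))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_identical(res$df, 1L)

  # transcription-factor table among downregulated genes
  tab <- c(17, 127, 1112, 15756)
  res <- chi_squared_2x2(tab)
  ref <- suppressWarnings(stats::chisq.test(matrix(tab, 2, byrow = TRUE),
                                            correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p.value, unname(ref$p.value), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:50) {
    tab <- as.vector(stats::rmultinom(1, sample(20:200, 1), c(.3, .2, .3, .2))) + 1
    m <- matrix(tab, 2, byrow = TRUE)
    expect_equal(chi_squared_2x2(tab)$statistic,
                 unname(suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-10)
    expect_equal(chi_squared_2x2(tab, yates = TRUE)$statistic,
                 unname(suppressWarnings(stats::chisq.test(m, correct = TRUE))$statistic),
                 tolerance = 1e-10)
  }

  expect_error(chi_squared_2x2(c(0, 0, 3, 4)), "zero margin")
})

test_that("overlap_fisher builds the published-style contingency table", {
  universe <- sprintf("G%05d", 1:17012)
  shared <- universe[1:29]
  mouse <- c(shared, universe[30:224])          # 224 mapped model genes
  human <- c(shared, universe[225:391])         # 196 human signature genes
  res <- overlap_fisher(mouse, human, universe)
  expect_equal(unname(res$table), c(29, 195, 167, 16621))
  expect_equal(sum(res$table), length(universe))
  expect_lt(res$p.value, 1e-4)

  # identical sets: maximal d cell, minimal p for the margins
  res_eq <- overlap_fisher(universe[1:20], universe[1:20], universe[1:200])
  expect_equal(unname(res_eq$table), c(20, 0, 0, 180))
  expect_lt(res_eq$p.value, 1e-10)

  # small disjoint sets in a big universe: no enrichment
  res_dj <- overlap_fisher(universe[1:5], universe[6:10], universe[1:1000])
  expect_true(res_dj$p.value > 0.9 || res_dj$odds.ratio < 1)

  expect_error(overlap_fisher(c("NOT_THERE"), universe[1:5], universe[1:100]),
               "outside the universe")
})

test_that("overlap cells always sum to the universe size", {
  set.seed(3)
  universe <- sprintf("g%03d", 1:120)
  for (i in 1:20) {
    a <- sample(universe, sample(0:40, 1))
    b <- sample(universe, sample(1:40, 1))
    expect_equal(sum(overlap_fisher(a, b, universe)$table), 120)
  }
})

test_that("map_homologs keeps in-universe homologs and counts the rest", {
  map <- data.frame(mouse = c("Gfap", "Vim", "Apoe"),
                    human = c("GFAP", "VIM", "APOE"))
  res <- map_homologs(c("Gfap", "Xyz1"), map, universe = "GFAP")
  expect_equal(res$mapped, "GFAP")
  expect_equal(res$n_unmapped, 1L)

  res <- map_homologs(character(0), map, universe = "GFAP")
  expect_equal(res$mapped, character(0))
  expect_equal(res$n_unmapped, 0L)

  expect_error(map_homologs("Gfap", map, universe = character(0)), "empty")
})

test_that("a homology table with the published mapping rate maps 254 to 224", {
  # synthetic stand-in for the 5xFAD signature: 254 mouse genes of which
  # 224 (210 up, 14 down) have human homologs inside the universe
  universe <- sprintf("HG%04d", 1:1000)
  mouse_mapped <- sprintf("mg%04d", 1:224)
  mouse_unmapped <- sprintf("mx%04d", 1:30)
  map <- data.frame(mouse = mouse_mapped, human = universe[1:224])
  genes <- c(mouse_mapped, mouse_unmapped)
  dirs <- c(rep("up", 210), rep("down", 14), rep("up", 29), "down")
  res <- map_homologs(genes, map, universe, directions = dirs)
  expect_length(res$mapped, 224)
  expect_equal(res$n_unmapped, 30L)
  expect_equal(unname(res$direction["up"]), 210L)
  expect_equal(unname(res$direction["down"]), 14L)
})

test_that("tf_enrichment reproduces the published-style 2x2 and errors on bad input", {
  universe <- sprintf("G%05d", 1:17012)
  tfs <- universe[1:1129]
  down <- c(universe[1:17], universe[2000:2126])    # 17 TFs of 144
  up <- c(universe[18], universe[3000:3050])        # 1 TF of 52
  res <- tf_enrichment(list(up = up, down = down), tfs, universe)
  dn <- res[res$list_name == "down", ]
  expect_equal(unname(unlist(dn[c("a", "b", "c", "d")])), c(17, 127, 1112, 15756))
  expect_equal(dn$statistic,
               chi_squared_2x2(c(17, 127, 1112, 15756))$statistic)
  expect_equal(res$list_name, c("overall", "up", "down"))

  expect_error(tf_enrichment(character(0), tfs, universe), "empty signature")
  expect_error(tf_enrichment(universe[1:10], "NOT_A_GENE", universe),
               "no transcription factors")
})

test_that("ora_gene_sets ranks a self-set first and uses BH across sets", {
  universe <- sprintf("g%03d", 1:200)
  sig <- universe[1:20]
  coll <- list(self = sig, partial = universe[15:40], off = universe[100:130])
  res <- ora_gene_sets(sig, coll, universe)
  expect_equal(res$set[1], "self")
  expect_equal(res$p.value[res$set == "off"], 1)
  expect_equal(res$q.value, oracle_bh(res$p.value), tolerance = 1e-12)
  expect_error(ora_gene_sets(sig, list(), universe), "empty")
})

test_that("bh_adjust equals the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("read_gmt and read_homology_map parse their formats", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG4"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets$setA, c("G1", "G2", "G3"))
  expect_equal(sets$setB, "G4")

  hm <- tempfile(fileext = ".tsv")
  writeLines(c("mouse\thuman", "Gfap\tGFAP"), hm)
  expect_equal(read_homology_map(hm)$human, "GFAP")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "x\ty"), bad)
  expect_error(read_homology_map(bad), "mouse")
})
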