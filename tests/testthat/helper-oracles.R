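# Brute-force oracles, kept independent of the package implementations.

# two-sided Fisher p by enumerating every table with the observed margins,
# probabilities written directly in binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(support, lp, numeric(1)))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}

# step-up BH applied literally: sort, scale by m/i, enforce monotonicity
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# exhaustive two-sided rank-sum p over all assignments of the pooled
# midranks to group 1
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n + 1) / 2
  w_obs <- sum(r[seq_len(n1)])
  ws <- colSums(matrix(r[utils::combn(n, n1)], nrow = n1))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# small well-separated multi-population expression matrix for graph tests
make_blobs <- function(n_per = 100, centers = 4, dims = 20, sd = 0.5, seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(centers * dims, sd = 4), centers, dims)
  x <- do.call(rbind, lapply(seq_len(centers), function(i) {
    matrix(rnorm(n_per * dims, mean = rep(mu[i, ], each = n_per), sd = sd),
           n_per, dims)
  }))
  rownames(x) <- sprintf("C%04d", seq_len(nrow(x)))
  colnames(x) <- sprintf("D%02d", seq_len(dims))
  list(x = x, labels = rep(seq_len(centers), each = n_per))
}

# compact generator config for fast unit tests; `...` overrides any default
small_sim_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(nuclei_per_type = c(protoplasmic = 150L, fibrous = 80L,
                             doublet_neuron = 30L, doublet_oligo = 30L),
         n_genes = 400L, n_up = 20L, n_down = 40L, n_weak = 60L,
         n_markers_per_panel = 5L, seed = seed),
    list(...))
  do.call(simulation_config, args)
}
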