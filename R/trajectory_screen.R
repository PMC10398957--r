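# The core screen: rank-uniformize pseudotime so nuclei are evenly spread
# along the trajectory, regress every gene's (denoised) normalized
# log-expression on it, and threshold by effect size, variance explained and
# Bonferroni-corrected significance.

#' Screen configuration
#'
#' Thresholds of the trajectory regression screen: effect size
#' (`|beta| > beta_min`), variance explained (`R^2 > r2_min`) and
#' Bonferroni-corrected significance (`p_bonf < alpha`), plus the gene
#' exclusions applied to MA-style tables.
#'
#' @param beta_min minimum absolute slope (two-sided; the down program is as
#'   real as the up one).
#' @param r2_min minimum R^2.
#' @param alpha significance level after Bonferroni correction.
#' @param plot_exclusions genes dropped from MA-style tables (very high
#'   expressors such as MALAT1 dominate the mean-expression axis).
#' @param rank_scale `"unit"` rescales ranks to \[0, 1\]; `"raw"` uses raw
#'   midranks (changes beta's scale and hence the meaning of `beta_min`).
#' @return `screen_config` list.
#' @export
screen_config <- function(beta_min = 0.1, r2_min = 0.1, alpha = 0.05,
                          plot_exclusions = "MALAT1",
                          rank_scale = c("unit", "raw")) {
  stopifnot(beta_min >= 0, r2_min >= 0, alpha > 0, alpha < 1)
  structure(list(beta_min = beta_min, r2_min = r2_min, alpha = alpha,
                 plot_exclusions = plot_exclusions,
                 rank_scale = match.arg(rank_scale)),
            class = "screen_config")
}

#' Rank-uniformize pseudotime
#'
#' Maps pseudotime values to `(rank - 1) / (n - 1)` with midranks for ties,
#' producing an (absent ties) evenly spaced covariate on \[0, 1\] that is
#' invariant to any strictly monotone transform of the input.
#'
#' @param t numeric pseudotime values, `length(t) >= 2`.
#' @param scale `"unit"` or `"raw"` (raw midranks).
#' @return numeric vector, same order as `t`.
#' @export
rank_uniform <- function(t, scale = "unit") {
  if (length(t) < 2) stop("need at least two nuclei", call. = FALSE)
  r <- rank(t, ties.method = "average")
  if (scale == "raw") return(r)
  (r - 1) / (length(t) - 1)
}

#' Per-gene linear regression on ranked pseudotime
#'
#' Ordinary least squares of every gene's expression on the ranked
#' pseudotime, with two-sided slope p-values from the t distribution on
#' `n - 2` degrees of freedom and Bonferroni correction over the tested
#' genes. Constant genes get `beta = 0`, `R^2 = 0`, `p = 1`.
#'
#' @param expr nuclei x genes expression matrix (normalized log scale,
#'   denoised upstream if desired), rows aligned with `ranked_t`.
#' @param ranked_t ranked pseudotime from [rank_uniform()].
#' @param config a [screen_config()].
#' @return data.frame (one row per gene): gene, beta, r2, p_raw, p_bonf,
#'   mean_expr, status in `{up, down, ns}`.
#' @export
gene_trajectory_regression <- function(expr, ranked_t, config = screen_config()) {
  expr <- as_dense(expr)
  n <- nrow(expr)
  stopifnot(length(ranked_t) == n)
  if (var(ranked_t) == 0) stop("ranked pseudotime has zero variance", call. = FALSE)
  x <- ranked_t - mean(ranked_t)
  sxx <- sum(x^2)
  xy <- crossprod(x, expr)[1, ]                 # sum x * (y - ybar) since sum x = 0
  beta <- xy / sxx
  mean_expr <- colMeans(expr)
  syy <- colSums(expr^2) - n * mean_expr^2
  ssr <- beta^2 * sxx
  sse <- pmax(0, syy - ssr)
  r2 <- ifelse(syy > 0, pmin(1, ssr / syy), 0)
  beta[syy == 0] <- 0
  se2 <- sse / (n - 2) / sxx
  tstat <- ifelse(se2 > 0, beta / sqrt(se2), ifelse(beta == 0, 0, Inf))
  p_raw <- ifelse(syy > 0, 2 * pt(-abs(tstat), df = n - 2), 1)
  m <- ncol(expr)
  records <- data.frame(
    gene = colnames(expr) %||% as.character(seq_len(m)),
    beta = as.numeric(beta), r2 = as.numeric(r2),
    p_raw = as.numeric(p_raw), p_bonf = pmin(1, as.numeric(p_raw) * m),
    mean_expr = as.numeric(mean_expr), stringsAsFactors = FALSE, row.names = NULL)
  records$status <- screen_status(records, config)
  records
}

screen_status <- function(records, config) {
  sig <- records$r2 > config$r2_min & records$p_bonf < config$alpha
  ifelse(sig & records$beta > config$beta_min, "up",
         ifelse(sig & records$beta < -config$beta_min, "down", "ns"))
}

#' Classify dysregulated genes
#'
#' Applies the screen thresholds to a record table and returns the up/down
#' signature.
#'
#' @param records output of [gene_trajectory_regression()].
#' @param config a [screen_config()].
#' @return list with `up` and `down` gene vectors and the re-thresholded
#'   `records`.
#' @export
classify_dysregulated <- function(records, config = screen_config()) {
  records$status <- screen_status(records, config)
  list(up = records$gene[records$status == "up"],
       down = records$gene[records$status == "down"],
       records = records)
}

#' MA-style table
#'
#' Rows for the mean-expression-vs-beta (and beta-vs-R^2) views: records
#' minus the configured exclusions and minus genes that are not significant
#' after Bonferroni correction.
#'
#' @param records output of [gene_trajectory_regression()].
#' @param config a [screen_config()].
#' @return data.frame: gene, mean_expr, beta, r2, status.
#' @export
ma_table <- function(records, config = screen_config()) {
  keep <- !(records$gene %in% config$plot_exclusions) &
    records$p_bonf < config$alpha
  out <- records[keep, c("gene", "mean_expr", "beta", "r2", "status")]
  rownames(out) <- NULL
  out
}
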