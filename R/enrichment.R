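# Exact-test primitives shared by the cross-signature comparisons
# (mouse-model overlaps, GWAS overlays, transcription-factor enrichment),
# the over-representation stage and the immunofluorescence statistics.

as_2x2 <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4) stop("a 2x2 table requires exactly four cells", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("2x2 cells must be non-negative finite counts", call. = FALSE)
  }
  if (any(x != round(x))) stop("2x2 cells must be integers", call. = FALSE)
  if (sum(x) <= 0) stop("2x2 table total must be positive", call. = FALSE)
  # column-major order of matrix(c(a,c,b,d)) vs flat c(a,b,c,d): accept both a
  # matrix (read row-wise a,b / c,d) and a flat vector c(a,b,c,d).
  if (is.matrix(table)) x <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  names(x) <- c("a", "b", "c", "d")
  x
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the usual two-sided definition: the p-value
#' is the sum of probabilities of all tables with the observed margins whose
#' probability does not exceed the observed table's. The odds ratio reported
#' is the sample cross-product ratio `ad/bc` (infinite when `b*c = 0` and
#' `a*d > 0`).
#'
#' @param table 2x2 matrix or length-4 vector `c(a, b, c, d)` giving counts
#'   row-wise: `a` and `b` are the first row, `c` and `d` the second.
#' @return list with `p.value`, `odds.ratio`, and the cell counts `table`.
#' @examples
#' fisher_exact_2x2(c(29, 195, 167, 16621))
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as_2x2(table)
  a <- x[["a"]]; b <- x[["b"]]; cc <- x[["c"]]; d <- x[["d"]]
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * cc)
  }
  list(p.value = min(1, p), odds.ratio = or, table = x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Closed-form Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom, with an
#' optional Yates continuity correction.
#'
#' @inheritParams fisher_exact_2x2
#' @param yates apply the continuity correction.
#' @return list with `statistic`, `p.value`, `df` (always 1), `table`.
#' @export
chi_squared_2x2 <- function(table, yates = FALSE) {
  x <- as_2x2(table)
  a <- x[["a"]]; b <- x[["b"]]; cc <- x[["c"]]; d <- x[["d"]]
  n <- a + b + cc + d
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) stop("chi-squared undefined: zero margin", call. = FALSE)
  dev <- abs(a * d - b * cc)
  if (yates) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / prod(margins)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, table = x)
}

#' Map mouse genes into the human analysis universe
#'
#' Keeps genes with a homolog whose human symbol lies in the analysis gene
#' universe; the rest are counted as unmapped. Direction labels (up/down),
#' when given, are carried through and tallied.
#'
#' @param genes character vector of mouse symbols.
#' @param map data.frame with columns `mouse` and `human` (extra columns
#'   ignored), or a named character vector `mouse -> human`.
#' @param universe character vector of human symbols defining the analysis
#'   transcriptome.
#' @param directions optional character vector parallel to `genes`
#'   (`"up"`/`"down"`).
#' @return list with `mapped` (human symbols, unique, in-universe),
#'   `n_unmapped`, and `direction` (named table of mapped counts by
#'   direction, when directions were supplied).
#' @export
map_homologs <- function(genes, map, universe, directions = NULL) {
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  if (is.data.frame(map)) {
    lookup <- setNames(as.character(map$human), as.character(map$mouse))
  } else {
    lookup <- map
  }
  if (length(genes) == 0) {
    return(list(mapped = character(0), n_unmapped = 0L, direction = NULL))
  }
  human <- unname(lookup[genes])
  ok <- !is.na(human) & human %in% universe
  dir_tab <- NULL
  if (!is.null(directions)) {
    stopifnot(length(directions) == length(genes))
    dir_tab <- table(factor(directions[ok], levels = c("up", "down")))
  }
  mapped <- human[ok]
  keep <- !duplicated(mapped)
  list(mapped = mapped[keep], n_unmapped = sum(!ok), direction = dir_tab)
}

#' Overlap Fisher test between two gene sets
#'
#' Builds the 2x2 table `a = |A ∩ B|`, `b = |A \\ B|`, `c = |B \\ A|`,
#' `d = |universe \\ (A ∪ B)|` and applies [fisher_exact_2x2()].
#'
#' @param set_a,set_b character vectors, both subsets of `universe`.
#' @param universe background gene universe.
#' @return list with the contingency `table` (a, b, c, d), `p.value`,
#'   `odds.ratio`.
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  bad <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(bad) > 0) {
    stop("genes outside the universe: ", paste(head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  cc <- length(set_b) - a
  d <- length(universe) - a - b - cc
  res <- fisher_exact_2x2(c(a, b, cc, d))
  res$table <- c(a = a, b = b, c = cc, d = d)
  res
}

#' Transcription-factor enrichment in a signature
#'
#' For a gene signature (optionally split by direction), builds the 2x2 of
#' TF vs non-TF membership against the remaining universe and applies the
#' chi-squared test, mirroring how TF over-representation is typically
#' assessed among dysregulated genes.
#'
#' @param signature character vector, or a list with elements `up` and
#'   `down`; all genes must lie in `universe`.
#' @param tf_list character vector of transcription-factor symbols.
#' @param universe background gene universe.
#' @param yates continuity correction flag passed through.
#' @return data.frame with one row per tested list (`overall` plus `up` and
#'   `down` when supplied): cell counts, chi-squared statistic, p, odds ratio.
#' @export
tf_enrichment <- function(signature, tf_list, universe, yates = FALSE) {
  tf_in <- intersect(tf_list, universe)
  if (length(tf_in) == 0) stop("no transcription factors in universe", call. = FALSE)
  sets <- if (is.list(signature)) {
    c(list(overall = unique(unlist(signature, use.names = FALSE))), signature)
  } else {
    list(overall = signature)
  }
  rows <- lapply(names(sets), function(nm) {
    sig <- unique(sets[[nm]])
    if (length(sig) == 0) stop("empty signature: ", nm, call. = FALSE)
    a <- length(intersect(sig, tf_in))
    b <- length(sig) - a
    cc <- length(tf_in) - a
    d <- length(universe) - length(sig) - cc
    cs <- chi_squared_2x2(c(a, b, cc, d), yates = yates)
    or <- if (b * cc == 0) NA_real_ else (a * d) / (b * cc)
    data.frame(list_name = nm, a = a, b = b, c = cc, d = d,
               statistic = cs$statistic, p.value = cs$p.value,
               odds.ratio = or, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Over-representation analysis against a gene-set collection
#'
#' One-sided (enrichment) Fisher test of a signature against every set in a
#' collection, restricted to the analysis universe, with Benjamini-Hochberg
#' adjustment across sets.
#'
#' @param signature character vector of genes, subset of `universe`.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background gene universe.
#' @return data.frame: set, set size in universe, overlap, p, BH q, odds
#'   ratio; ordered by p.
#' @export
ora_gene_sets <- function(signature, collection, universe) {
  if (length(collection) == 0) stop("empty gene-set collection", call. = FALSE)
  signature <- unique(intersect(signature, universe))
  n <- length(unique(universe))
  k <- length(signature)
  rows <- lapply(names(collection), function(nm) {
    set <- unique(intersect(collection[[nm]], universe))
    a <- length(intersect(signature, set))
    m <- length(set)
    # one-sided enrichment: P(overlap >= a)
    p <- phyper(a - 1, m, n - m, k, lower.tail = FALSE)
    b <- k - a; cc <- m - a; d <- n - k - cc
    or <- if (b * cc == 0) NA_real_ else (a * d) / (b * cc)
    data.frame(set = nm, n_set = m, n_overlap = a, p.value = p,
               odds.ratio = or, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q.value <- bh_adjust(out$p.value)
  out[order(out$p.value), c("set", "n_set", "n_overlap", "p.value", "q.value",
                            "odds.ratio")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, capped at 1).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-delimited: set name, description, genes).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read a two-column mouse-to-human homology table
#'
#' @param path TSV with columns `mouse` and `human` (header required).
#' @return data.frame with those columns.
#' @export
read_homology_map <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mouse", "human") %in% names(m))) {
    stop("homology table needs 'mouse' and 'human' columns", call. = FALSE)
  }
  m[, c("mouse", "human")]
}
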