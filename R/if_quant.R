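# Immunofluorescence count statistics: pool marker-positive counts across
# donors and images within each group, then compare the pooled proportions
# with Fisher's exact test.

#' Pool immunofluorescence counts per group
#'
#' Sums positive and denominator counts for one marker across donors and
#' images within each group and returns the group x positive/negative 2x2
#' table.
#'
#' @param table data.frame with columns `donor`, `group`, `marker`,
#'   `positive`, `total` (an `image` column is allowed and ignored by the
#'   pooling).
#' @param marker marker to pool (must be present).
#' @param groups the two groups to compare (default the two levels found,
#'   sorted).
#' @return 2x2 integer matrix, rows = groups, cols = c("positive",
#'   "negative").
#' @export
pool_counts <- function(table, marker, groups = NULL) {
  req <- c("donor", "group", "marker", "positive", "total")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols) > 0) {
    stop("count table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(table$positive > table$total | table$positive < 0)
  if (length(bad) > 0) {
    stop("positive exceeds denominator (or is negative) in row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tab <- table[table$marker == marker, ]
  if (nrow(tab) == 0) stop("no rows for marker ", marker, call. = FALSE)
  groups <- groups %||% sort(unique(tab$group))
  if (length(unique(tab$group)) < 2 || !all(groups %in% tab$group)) {
    stop("both groups must be present for marker ", marker, call. = FALSE)
  }
  pos <- tapply(tab$positive, tab$group, sum)[groups]
  tot <- tapply(tab$total, tab$group, sum)[groups]
  out <- cbind(positive = as.integer(pos), negative = as.integer(tot - pos))
  rownames(out) <- groups
  out
}

#' Compare pooled marker proportions between groups
#'
#' Two-sided Fisher's exact test on a pooled 2x2 from [pool_counts()], with
#' per-group proportions (reported to 3 decimals) and the sample odds ratio.
#'
#' @param pooled 2x2 matrix, rows = groups, cols = positive/negative.
#' @return list with `proportions` (named, rounded to 3 decimals),
#'   `odds.ratio`, `p.value`, `table`.
#' @export
compare_proportions <- function(pooled) {
  stopifnot(is.matrix(pooled), nrow(pooled) == 2, ncol(pooled) == 2)
  denom <- rowSums(pooled)
  if (any(denom == 0)) stop("zero denominator in a group", call. = FALSE)
  fis <- fisher_exact_2x2(c(pooled[1, 1], pooled[1, 2], pooled[2, 1], pooled[2, 2]))
  props <- round(pooled[, 1] / denom, 3)
  list(proportions = props, odds.ratio = fis$odds.ratio,
       p.value = fis$p.value, table = pooled)
}

#' Read an immunofluorescence count table
#'
#' @param path TSV with columns donor, group, image, marker, positive, total.
#' @return data.frame.
#' @export
read_if_counts <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
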