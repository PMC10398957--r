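# Plain-text I/O: MatrixMarket counts with gene/barcode sidecars, TSV
# metadata and results, and a YAML run manifest.

#' Write a dataset to MTX + TSV files
#'
#' Writes `matrix.mtx` (MatrixMarket, 1-based indices), `genes.tsv`,
#' `barcodes.tsv`, `metadata.tsv` and, for synthetic data, `truth_nuclei.tsv`
#' and `truth_genes.tsv`, plus a `manifest.yaml` recording the seed.
#'
#' @param dataset a `synthetic_dataset`, or a list with `counts` and `meta`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- as_sparse_counts(dataset$counts)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  write_tsv(dataset$meta, file.path(dir, "metadata.tsv"))
  if (!is.null(dataset$truth)) {
    write_tsv(dataset$truth$nuclei, file.path(dir, "truth_nuclei.tsv"))
    write_tsv(dataset$truth$genes, file.path(dir, "truth_genes.tsv"))
  }
  manifest <- list(seed = if (!is.null(dataset$config)) dataset$config$seed else NA,
                   n_nuclei = nrow(counts), n_genes = ncol(counts))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read counts written by [write_dataset()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return sparse nuclei x genes count matrix with dimnames.
#' @export
read_count_matrix <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  colnames(m) <- readLines(file.path(dir, "genes.tsv"))
  m
}

#' @rdname read_count_matrix
#' @export
read_nucleus_meta <- function(dir) {
  read.delim(file.path(dir, "metadata.tsv"), stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
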