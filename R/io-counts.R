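#' Write a count matrix as an MTX triplet
#'
#' Writes `matrix.mtx` (MatrixMarket), `genes.tsv` (gene, mito flag) and
#' `barcodes.tsv` (cell, sample, cluster, covariates) into `dir`.
#'
#' @param x a [count_matrix()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write.table(data.frame(gene = x$gene_names, mito = as.integer(x$mito)),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  bc <- data.frame(cell = x$cell_names, sample = x$sample,
                   cluster = x$cluster)
  if (!is.null(x$covariates)) {
    bc <- cbind(bc, x$covariates[, setdiff(names(x$covariates), "cell"),
                                 drop = FALSE])
  }
  write.table(bc, file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix from an MTX triplet
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   as written by [write_counts_mtx()].
#' @return a [count_matrix()].
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- read.delim(file.path(dir, "genes.tsv"))
  bc <- read.delim(file.path(dir, "barcodes.tsv"))
  rownames(m) <- genes$gene
  colnames(m) <- bc$cell
  cov_cols <- setdiff(names(bc), c("cell", "sample", "cluster"))
  count_matrix(m, mito = genes$mito == 1,
               sample = bc$sample, cluster = bc$cluster,
               covariates = if (length(cov_cols)) {
                 cbind(data.frame(cell = bc$cell),
                       bc[, cov_cols, drop = FALSE])
               })
}

#' Write / read a dense TSV count matrix
#'
#' Genes in rows (first column `gene`), cells in columns. Mito flags are
#' recovered from the `MT-` gene-name prefix on read unless supplied.
#'
#' @param x a [count_matrix()].
#' @param path TSV file.
#' @return `path` invisibly (write); a [count_matrix()] (read).
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- cbind(data.frame(gene = x$gene_names), as.matrix(x$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param mito optional logical per-gene flag.
#' @export
read_counts_tsv <- function(path, mito = NULL) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  count_matrix(m, mito = mito %||% startsWith(df$gene, "MT-"))
}
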