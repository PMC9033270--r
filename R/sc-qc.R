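#' Per-cell quality-control metrics
#'
#' @param x a [count_matrix()].
#' @return data.frame with `cell`, `total_counts`, `detected_genes`,
#'   `mito_fraction`.
#' @export
cell_qc_metrics <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (!any(x$mito)) {
    stop_config("no mitochondrial genes flagged; mito_fraction undefined")
  }
  tot <- Matrix::colSums(x$counts)
  data.frame(
    cell = x$cell_names,
    total_counts = as.integer(tot),
    detected_genes = as.integer(Matrix::colSums(x$counts > 0)),
    mito_fraction = as.numeric(Matrix::colSums(x$counts[x$mito, , drop = FALSE]) /
                                 pmax(tot, 1)),
    row.names = NULL
  )
}

#' Quality-control filtering of cells
#'
#' A cell passes iff `total_counts > min_counts` AND `detected_genes >
#' min_genes` AND `mito_low < mito_fraction < mito_high`, all strict
#' inequalities. Defaults are the standard cutoffs for these neuruloid
#' dissociates: counts > 6000, genes > 2600, 3% < mitochondrial fraction
#' < 11%. Idempotent: filtering a filtered matrix changes nothing.
#'
#' @param x a [count_matrix()].
#' @param min_counts,min_genes,mito_low,mito_high the cutoffs.
#' @return list with `matrix` (passing cells) and `qc` (per-cell records for
#'   all input cells: metrics, `pass`, `failed_rules` — comma-joined rule
#'   names, empty when passing).
#' @export
qc_filter <- function(x, min_counts = 6000, min_genes = 2600,
                      mito_low = 0.03, mito_high = 0.11) {
  qc <- cell_qc_metrics(x)
  fails <- cbind(
    counts = !(qc$total_counts > min_counts),
    genes = !(qc$detected_genes > min_genes),
    mito_low = !(qc$mito_fraction > mito_low),
    mito_high = !(qc$mito_fraction < mito_high)
  )
  qc$failed_rules <- apply(fails, 1, function(f) {
    paste(colnames(fails)[f], collapse = ",")
  })
  qc$pass <- qc$failed_rules == ""
  list(matrix = subset_cells(x, qc$pass), qc = qc)
}

#' Library-size normalization with log10 transform
#'
#' `log10(1 + count * scale_total / cell_total)`: counts are rescaled to a
#' common library size and log10-transformed (zero counts map to 0).
#'
#' @param x a [count_matrix()] or a genes-by-cells matrix.
#' @param scale_total target library size (default 1e4).
#' @return dense numeric genes-by-cells matrix; cells with zero total get all
#'   zeros and are listed in the `zero_total_cells` attribute.
#' @export
normalize_log <- function(x, scale_total = 1e4) {
  stopifnot(scale_total > 0)
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  tot <- Matrix::colSums(counts)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts; values set to 0")
  }
  dense <- as.matrix(counts)
  out <- log10(1 + sweep(dense, 2, ifelse(zero, 1, tot / scale_total), `/`))
  out[, zero] <- 0
  dimnames(out) <- dimnames(counts)
  attr(out, "zero_total_cells") <- colnames(counts)[zero]
  out
}

#' Residualize expression on per-cell covariates
#'
#' Per gene, replaces expression by the residuals of an ordinary
#' least-squares fit on the covariates (plus intercept), re-centered at the
#' gene's original mean — the "rescaling" used to remove cell-cycle and
#' mitochondrial-content effects before downstream comparisons. Collinear
#' covariates are dropped with a warning.
#'
#' @param expr dense genes-by-cells matrix (e.g. from [normalize_log()]).
#' @param covariates data.frame or matrix of per-cell covariates (cells in
#'   rows, same order as `expr` columns); each must be finite with at least 2
#'   distinct values.
#' @return matrix of the same shape.
#' @export
regress_covariates <- function(expr, covariates) {
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == ncol(expr))
  if (!all(is.finite(covariates))) stop_config("covariates must be finite")
  nd <- apply(covariates, 2, function(v) length(unique(v)))
  if (any(nd < 2)) {
    stop_config("covariate(s) with fewer than 2 distinct values: ",
                paste(colnames(covariates)[nd < 2], collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping collinear covariate(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
    qrX <- qr(X)
  }
  res <- t(qr.resid(qrX, t(expr)))
  res + rowMeans(expr)
}
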