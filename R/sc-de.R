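#' Marker-signature lineage scoring
#'
#' Per lineage, scores each cell as the mean normalized expression of the
#' lineage's marker genes minus the mean of a size-matched random background
#' gene set (fixed seed), then labels each cell by the best-scoring lineage.
#' Cells whose top-two score gap is below `margin` are labelled NA.
#'
#' @param expr dense genes-by-cells matrix (normalized).
#' @param marker_sets named list: lineage -> marker gene names. Genes absent
#'   from `expr` are dropped with a warning; an empty set after filtering is
#'   an error.
#' @param margin minimum top-two gap for a confident label.
#' @param seed seed for the background draw.
#' @return list with `labels` (per-cell character, NA where ambiguous) and
#'   `scores` (cells x lineages matrix).
#' @export
score_lineage <- function(expr, marker_sets, margin = 1e-6, seed = 1) {
  stopifnot(is.list(marker_sets), length(marker_sets) >= 2)
  genes <- rownames(expr)
  all_markers <- unlist(marker_sets, use.names = FALSE)
  pool <- setdiff(genes, all_markers)
  scores <- with_seed(seed, {
    vapply(names(marker_sets), function(nm) {
      present <- intersect(marker_sets[[nm]], genes)
      missing <- setdiff(marker_sets[[nm]], genes)
      if (length(missing)) {
        warning("lineage ", nm, ": ", length(missing),
                " marker gene(s) absent, dropped")
      }
      if (length(present) == 0) {
        stop_config("lineage ", nm, ": no marker genes present")
      }
      bg <- sample(pool, min(length(present), length(pool)))
      colMeans(expr[present, , drop = FALSE]) -
        colMeans(expr[bg, , drop = FALSE])
    }, numeric(ncol(expr)))
  })
  scores <- matrix(scores, ncol = length(marker_sets),
                   dimnames = list(colnames(expr), names(marker_sets)))
  top <- apply(scores, 1, function(s) {
    o <- order(s, decreasing = TRUE)
    c(best = o[1], gap = unname(s[o[1]] - s[o[2]]))
  })
  labels <- colnames(scores)[top["best", ]]
  labels[top["gap", ] < margin] <- NA_character_
  list(labels = setNames(labels, colnames(expr)), scores = scores)
}

#' Hurdle-model differential expression between two cell groups
#'
#' Per gene, a two-part (hurdle) model on normalized expression: a logistic
#' regression of detection (expression > 0) on group, and a Gaussian linear
#' model of the positive values on group, each optionally adjusted for the
#' cellular detection rate (CDR, the fraction of genes detected per cell).
#' The hurdle p-value comes from the sum of the two likelihood-ratio
#' chi-square statistics with summed degrees of freedom; a component whose
#' design is degenerate (all-or-none detection; too few or single-group
#' positives) contributes zero statistic and zero df. Genes detected in fewer
#' than `min_cells` cells overall are flagged untestable with p = 1.
#'
#' Log fold changes are differences of group means of the (log10-scale)
#' normalized expression, so they are log10 fold changes.
#'
#' @param expr dense genes-by-cells normalized matrix.
#' @param cells_a,cells_b cell names or indices of the two groups (log fold
#'   change is mean(A) − mean(B)).
#' @param adjust_cdr include the CDR covariate (default TRUE).
#' @param min_cells minimum detected cells for a testable gene (default 3).
#' @return data.frame with `gene`, `log_fc`, `p_disc`, `p_cont`, `p_hurdle`,
#'   `fdr` (BH across genes), `n_a`, `n_b`, `testable`.
#' @export
hurdle_de <- function(expr, cells_a, cells_b, adjust_cdr = TRUE,
                      min_cells = 3) {
  ia <- resolve_cells(expr, cells_a)
  ib <- resolve_cells(expr, cells_b)
  if (length(ia) == 0 || length(ib) == 0) {
    stop_config("both groups must be non-empty")
  }
  if (length(intersect(ia, ib))) stop_config("groups overlap")
  cells <- c(ia, ib)
  grp <- c(rep(1, length(ia)), rep(0, length(ib)))
  sub <- expr[, cells, drop = FALSE]
  cdr <- colMeans(sub > 0)
  X1 <- if (adjust_cdr) cbind(1, grp, scale(cdr)) else cbind(1, grp)
  X0 <- X1[, -2, drop = FALSE]
  ng <- nrow(sub)
  log_fc <- rowMeans(sub[, grp == 1, drop = FALSE]) -
    rowMeans(sub[, grp == 0, drop = FALSE])
  p_disc <- p_cont <- rep(NA_real_, ng)
  p_hurdle <- rep(1, ng)
  testable <- rep(FALSE, ng)
  for (i in seq_len(ng)) {
    y <- sub[i, ]
    d <- as.numeric(y > 0)
    npos <- sum(d)
    if (npos < min_cells) next
    chi <- 0; df <- 0L
    if (npos < length(d)) {
      lr <- binomial_lrt(X1, X0, d)
      if (!is.null(lr)) {
        chi <- chi + lr$chi; df <- df + 1L
        p_disc[i] <- pchisq(lr$chi, 1, lower.tail = FALSE)
      }
    }
    pos <- d > 0
    if (npos >= ncol(X1) + 1 && length(unique(grp[pos])) == 2) {
      lr <- gaussian_lrt(X1[pos, , drop = FALSE], X0[pos, , drop = FALSE],
                         y[pos])
      if (!is.null(lr)) {
        chi <- chi + lr$chi; df <- df + 1L
        p_cont[i] <- pchisq(lr$chi, 1, lower.tail = FALSE)
      }
    }
    if (df > 0) {
      testable[i] <- TRUE
      p_hurdle[i] <- pchisq(chi, df, lower.tail = FALSE)
    }
  }
  out <- data.frame(gene = rownames(sub), log_fc = log_fc,
                    p_disc = p_disc, p_cont = p_cont, p_hurdle = p_hurdle,
                    fdr = p.adjust(p_hurdle, "BH"),
                    n_a = length(ia), n_b = length(ib),
                    testable = testable, row.names = NULL)
  attr(out, "adjust_cdr") <- adjust_cdr
  attr(out, "lfc_base") <- "log10"
  out
}

resolve_cells <- function(expr, cells) {
  if (is.character(cells)) {
    idx <- match(cells, colnames(expr))
    if (anyNA(idx)) stop_config("unknown cell names")
    idx
  } else if (is.logical(cells)) {
    which(cells)
  } else as.integer(cells)
}

# LRT of the group term in a logistic model; NULL when the fit is degenerate.
binomial_lrt <- function(X1, X0, d) {
  f1 <- tryCatch(
    suppressWarnings(glm.fit(X1, d, family = binomial())),
    error = function(e) NULL)
  f0 <- tryCatch(
    suppressWarnings(glm.fit(X0, d, family = binomial())),
    error = function(e) NULL)
  if (is.null(f1) || is.null(f0) || !f1$converged || !f0$converged) return(NULL)
  list(chi = max(0, f0$deviance - f1$deviance))
}

# LRT of the group term in a Gaussian model (chi2 = n log(RSS0/RSS1)).
gaussian_lrt <- function(X1, X0, y) {
  r1 <- tryCatch(lm.fit(X1, y), error = function(e) NULL)
  r0 <- tryCatch(lm.fit(X0, y), error = function(e) NULL)
  if (is.null(r1) || is.null(r0)) return(NULL)
  rss1 <- sum(r1$residuals^2)
  rss0 <- sum(r0$residuals^2)
  if (rss1 <= .Machine$double.eps * max(1, rss0)) {
    # perfect fit: treat as a very large statistic, capped for stability
    return(list(chi = 700))
  }
  list(chi = max(0, length(y) * log(rss0 / rss1)))
}

# Per-gene signed z-statistics from a hurdle_de table (untestable -> NA).
de_zscores <- function(de, cap = 38) {
  z <- qnorm(pmax(de$p_hurdle, 1e-300) / 2, lower.tail = FALSE)
  z <- pmin(z, cap) * ifelse(de$log_fc >= 0, 1, -1)
  z[!de$testable] <- NA_real_
  setNames(z, de$gene)
}
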