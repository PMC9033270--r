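#' Permutation gene-set enrichment on hurdle-test statistics
#'
#' Scores a gene set as the mean signed z-statistic (derived from the hurdle
#' test of the stated contrast) over the set's genes, and assigns a
#' permutation p-value against size-matched random gene sets drawn from all
#' testable genes (a competitive null; fixed seed). The p-value uses the +1
#' correction, so it is never exactly 0:
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param x either a [hurdle_de()] result table, or a dense normalized
#'   expression matrix (then `cells_a` / `cells_b` define the contrast and
#'   the hurdle test is run here).
#' @param gene_set character vector of gene names.
#' @param cells_a,cells_b contrast groups (only when `x` is a matrix).
#' @param n_perm number of random sets (>= 999).
#' @param seed RNG seed for the permutations.
#' @param adjust_cdr passed to [hurdle_de()].
#' @param min_genes sets with fewer present genes are flagged low-coverage.
#' @param set_name label for the output row.
#' @return one-row data.frame: `set_name`, `score`, `p_perm`,
#'   `n_set_genes_present`, `low_coverage`.
#' @export
gene_set_enrichment <- function(x, gene_set, cells_a = NULL, cells_b = NULL,
                                n_perm = 999, seed = 1, adjust_cdr = TRUE,
                                min_genes = 5, set_name = "set") {
  stopifnot(n_perm >= 999)
  de <- if (is.data.frame(x)) x else {
    hurdle_de(x, cells_a, cells_b, adjust_cdr = adjust_cdr)
  }
  z <- de_zscores(de)
  z <- z[!is.na(z)]
  present <- intersect(gene_set, names(z))
  if (length(present) == 0) {
    stop_config("gene set has no testable genes in the data")
  }
  low <- length(present) < min_genes
  if (low) warning("gene set has < ", min_genes, " testable genes")
  obs <- mean(z[present])
  m <- length(present)
  null_scores <- with_seed(seed, {
    vapply(seq_len(n_perm), function(j) mean(z[sample.int(length(z), m)]),
           numeric(1))
  })
  # +1-corrected permutation p; exact ties (possible only for degenerate
  # sets) count half, so a set equal to the whole background sits mid-scale
  n_ge <- sum(null_scores > obs) + 0.5 * sum(null_scores == obs)
  data.frame(set_name = set_name, score = obs,
             p_perm = (1 + n_ge) / (n_perm + 1),
             n_set_genes_present = m, low_coverage = low,
             row.names = NULL)
}

#' Gene-set enrichment per lineage cluster
#'
#' For each cluster, runs the hurdle test for the stated sample contrast
#' within that cluster's cells and evaluates each gene set with
#' [gene_set_enrichment()]; BH FDR is computed across all (set, cluster)
#' pairs.
#'
#' @param expr dense normalized genes-by-cells matrix.
#' @param gene_sets named list of gene-name vectors (e.g. from [read_gmt()]).
#' @param cluster per-cell cluster labels (aligned with `expr` columns).
#' @param sample per-cell sample labels.
#' @param contrast length-2: `c(a, b)`; the score sign follows a − b (e.g.
#'   `c("HD", "WT")`).
#' @param clusters clusters to evaluate (default: all with cells in both
#'   samples).
#' @param n_perm,seed,adjust_cdr passed down.
#' @return data.frame with one row per (set, cluster): `set_name`, `cluster`,
#'   `score`, `p_perm`, `fdr`, `n_set_genes_present`, `low_coverage`.
#' @export
enrichment_by_cluster <- function(expr, gene_sets, cluster, sample,
                                  contrast = c("HD", "WT"),
                                  clusters = NULL, n_perm = 999, seed = 1,
                                  adjust_cdr = TRUE) {
  stopifnot(length(cluster) == ncol(expr), length(sample) == ncol(expr),
            length(contrast) == 2)
  if (is.null(clusters)) {
    clusters <- sort(unique(cluster[!is.na(cluster)]))
  }
  rows <- list()
  for (k in seq_along(clusters)) {
    cl <- clusters[k]
    in_cl <- !is.na(cluster) & cluster == cl
    ia <- which(in_cl & sample == contrast[1])
    ib <- which(in_cl & sample == contrast[2])
    if (length(ia) == 0 || length(ib) == 0) {
      warning("cluster ", cl, " lacks cells in one sample; skipped")
      next
    }
    de <- hurdle_de(expr, ia, ib, adjust_cdr = adjust_cdr)
    for (s in seq_along(gene_sets)) {
      r <- gene_set_enrichment(de, gene_sets[[s]],
                               n_perm = n_perm,
                               seed = seed + 1000L * k + s,
                               set_name = names(gene_sets)[s] %||%
                                 paste0("set", s))
      r$cluster <- cl
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_perm, "BH")
  out[, c("set_name", "cluster", "score", "p_perm", "fdr",
          "n_set_genes_present", "low_coverage")]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (tab-separated: set name, description, genes).
#' @return named list of gene-name vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_config("cannot read GMT: ", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene-name vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
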