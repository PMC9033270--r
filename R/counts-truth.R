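#' Default lineage marker gene lists
#'
#' Curated cell-type-specific markers for the three ectodermal lineages of a
#' day-4 neuruloid: neural ectoderm (NE; PAX6, SOX1, ...), neural crest (NC;
#' SOX10, FOXD3, ...) and early epidermis (E; KRT18, TFAP2A, ...).
#'
#' @return named list of gene-name vectors.
#' @export
default_marker_genes <- function() {
  list(
    NE = c("PAX6", "SOX1", "SOX2", "NES", "OTX2", "HES5", "SIX3", "LHX5",
           "FOXG1", "ZIC2", "SOX21", "FABP7"),
    NC = c("SOX10", "FOXD3", "PAX3", "TFAP2B", "SNAI2", "ZEB2", "NGFR",
           "PLP1", "ERBB3", "EDNRB", "MPZ", "S100B"),
    E  = c("KRT18", "TFAP2A", "KRT8", "GATA3", "DLX3", "KRT19", "CDH1",
           "GRHL2", "TFAP2C", "ISL1", "HAND1", "WNT6")
  )
}

#' Ground truth for a synthetic single-cell count matrix
#'
#' Parameterizes a negative-binomial genes-by-cells simulation with three
#' ectodermal lineage clusters (NE = neural ectoderm, NC = neural crest,
#' E = early epidermis) in one or more samples (WT / HD), per-cluster marker
#' genes, a plantable gene set with a per-(cluster, sample) expression shift
#' (a stand-in for a curated list of direct YAP targets), mitochondrial genes
#' calibrated to a target count fraction, a synthetic cell-cycle covariate,
#' and optionally planted low-quality cells that each violate one named QC
#' rule (including exact boundary cases at the strict cutoffs).
#'
#' Genes are simulated independently (no gene-gene correlation), which is
#' sufficient to calibrate the per-gene hurdle test and the per-set
#' enrichment.
#'
#' @param n_genes total number of genes (must accommodate markers, the
#'   planted set and mito genes).
#' @param n_cells_per_cluster named vector of cells per cluster, per sample.
#' @param samples sample labels (default `c("WT", "HD")`).
#' @param marker_genes named list of per-cluster marker gene names; default
#'   [default_marker_genes()]. Must be disjoint from the planted set.
#' @param marker_fold fold-up of a marker in its own cluster.
#' @param marker_off_factor residual factor in other clusters.
#' @param planted_set_size size of the plantable gene set (default 364, the
#'   size of the curated YAP-target list this emulates).
#' @param set_shift data.frame with columns `cluster`, `sample`, `log2_fc`
#'   giving the planted shift of the set (NA sample = all samples); NULL for
#'   no shift.
#' @param n_mito number of mitochondrial genes (names prefixed `MT-`).
#' @param mito_fraction_target expected mitochondrial count fraction of a
#'   normal cell (default 0.06, inside the 3–11% QC window).
#' @param mean_log_mu,sd_log_mu log-normal law of per-gene base means.
#' @param nb_size negative-binomial size (1 / dispersion) shared by all genes.
#' @param plant_bad_cells plant the 10 standard QC violators (see
#'   [make_counts()]).
#' @param seed integer seed; all gene-level randomness is consumed here.
#' @return object of class `counts_truth`.
#' @export
counts_truth <- function(n_genes = 4000,
                         n_cells_per_cluster = c(NE = 300, NC = 200, E = 300),
                         samples = c("WT", "HD"),
                         marker_genes = default_marker_genes(),
                         marker_fold = 8,
                         marker_off_factor = 0.05,
                         planted_set_size = 364,
                         set_shift = NULL,
                         n_mito = 50,
                         mito_fraction_target = 0.06,
                         mean_log_mu = log(2.5),
                         sd_log_mu = 1,
                         nb_size = 3,
                         plant_bad_cells = FALSE,
                         seed = 1) {
  stopifnot(nb_size > 0, n_mito >= 1, planted_set_size >= 0,
            !is.null(names(n_cells_per_cluster)))
  clusters <- names(n_cells_per_cluster)
  if (!setequal(names(marker_genes), clusters)) {
    stop_config("marker_genes must be named by the clusters: ",
                paste(clusters, collapse = ", "))
  }
  all_markers <- unlist(marker_genes, use.names = FALSE)
  if (anyDuplicated(all_markers)) {
    stop_config("marker gene lists must be disjoint across clusters")
  }
  planted_set <- if (planted_set_size > 0) {
    sprintf("YAPT%04d", seq_len(planted_set_size))
  } else character(0)
  if (length(intersect(planted_set, all_markers))) {
    stop_config("planted set and marker genes must be disjoint")
  }
  mito_genes <- sprintf("MT-M%03d", seq_len(n_mito))
  n_named <- length(all_markers) + length(planted_set) + n_mito
  if (n_genes < n_named + 100) {
    stop_config("n_genes too small for markers + planted set + mito genes")
  }
  filler <- sprintf("G%05d", seq_len(n_genes - n_named))
  gene_names <- c(all_markers, planted_set, mito_genes, filler)

  if (!is.null(set_shift)) {
    stopifnot(all(c("cluster", "log2_fc") %in% names(set_shift)))
    if (!"sample" %in% names(set_shift)) set_shift$sample <- NA_character_
    bad <- setdiff(set_shift$cluster, clusters)
    if (length(bad)) stop_config("set_shift clusters not simulated: ",
                                 paste(bad, collapse = ", "))
  }

  base_mu <- with_seed(seed, {
    mu <- rlnorm(n_genes, meanlog = mean_log_mu, sdlog = sd_log_mu)
    pmin(pmax(mu, 0.05), 50)
  })
  names(base_mu) <- gene_names
  # markers get a moderate, constant base expression
  base_mu[all_markers] <- 2
  # calibrate mito means to the target count fraction
  non_mito_sum <- sum(base_mu[setdiff(gene_names, mito_genes)])
  base_mu[mito_genes] <- non_mito_sum *
    mito_fraction_target / (1 - mito_fraction_target) / n_mito

  structure(list(
    n_genes = n_genes, gene_names = gene_names,
    n_cells_per_cluster = n_cells_per_cluster, clusters = clusters,
    samples = samples, marker_genes = marker_genes,
    marker_fold = marker_fold, marker_off_factor = marker_off_factor,
    planted_set = planted_set, set_shift = set_shift,
    mito_genes = mito_genes, mito_fraction_target = mito_fraction_target,
    base_mu = base_mu, nb_size = nb_size,
    plant_bad_cells = plant_bad_cells, seed = seed
  ), class = "counts_truth")
}

#' @export
print.counts_truth <- function(x, ...) {
  cat("counts_truth:", x$n_genes, "genes;",
      paste(names(x$n_cells_per_cluster), x$n_cells_per_cluster,
            sep = "=", collapse = ", "),
      "cells/cluster per sample (", paste(x$samples, collapse = ", "), ");",
      length(x$planted_set), "planted-set genes;",
      length(x$mito_genes), "mito genes\n")
  invisible(x)
}

# Per-gene NB mean vector for one (cluster, sample) condition.
condition_mu <- function(truth, cluster, sample) {
  mu <- truth$base_mu
  for (cl in truth$clusters) {
    mk <- truth$marker_genes[[cl]]
    mu[mk] <- mu[mk] * if (cl == cluster) truth$marker_fold else truth$marker_off_factor
  }
  if (!is.null(truth$set_shift)) {
    hit <- truth$set_shift$cluster == cluster &
      (is.na(truth$set_shift$sample) | truth$set_shift$sample == sample)
    for (i in which(hit)) {
      mu[truth$planted_set] <- mu[truth$planted_set] * 2^truth$set_shift$log2_fc[i]
    }
  }
  mu
}

#' Simulate a single-cell count matrix from its ground truth
#'
#' Draws gene-by-cell negative-binomial counts per (cluster, sample)
#' condition, emits a synthetic per-cell cell-cycle score covariate, and — when
#' the truth requests it — appends 10 planted low-quality cells, each
#' constructed to violate one named QC rule: totals of 3000 / 5000 / exactly
#' 6000 (strict `> 6000` boundary), detected genes 1000 / 2000 / exactly 2600,
#' and mitochondrial fractions 0.01 / exactly 0.03 / exactly 0.11 / 0.20.
#' Deterministic for a fixed truth.
#'
#' @param truth a [counts_truth()].
#' @param seed seed for the count draws (default: the truth's own seed).
#' @return list with `matrix` (a [count_matrix()]) and `truth` augmented with
#'   `cluster_of_cell` and `planted_bad_cells` (data.frame cell/rule).
#' @export
make_counts <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "counts_truth"))
  g <- truth$n_genes
  blocks <- list(); cl_lab <- character(0); sm_lab <- character(0)
  with_seed(seed, {
    for (sm in truth$samples) {
      for (cl in truth$clusters) {
        ncell <- truth$n_cells_per_cluster[[cl]]
        mu <- condition_mu(truth, cl, sm)
        m <- matrix(rnbinom(g * ncell, mu = mu, size = truth$nb_size),
                    nrow = g)
        blocks[[length(blocks) + 1L]] <- m
        cl_lab <- c(cl_lab, rep(cl, ncell))
        sm_lab <- c(sm_lab, rep(sm, ncell))
      }
    }
    counts <- do.call(cbind, blocks)
    rownames(counts) <- truth$gene_names
    colnames(counts) <- sprintf("%s_%s_%04d", sm_lab, cl_lab,
                                seq_along(cl_lab))
    bad <- NULL
    if (isTRUE(truth$plant_bad_cells)) {
      planted <- plant_bad_cells(truth)
      counts <- cbind(counts, planted$counts)
      cl_lab <- c(cl_lab, rep(truth$clusters[1], ncol(planted$counts)))
      sm_lab <- c(sm_lab, rep(truth$samples[1], ncol(planted$counts)))
      bad <- planted$table
    }
    cc_score <- rnorm(ncol(counts))
    mat <- count_matrix(
      counts = counts,
      mito = truth$gene_names %in% truth$mito_genes,
      sample = sm_lab, cluster = cl_lab,
      covariates = data.frame(cell = colnames(counts), cc_score = cc_score)
    )
    truth$cluster_of_cell <- setNames(cl_lab, colnames(counts))
    truth$planted_bad_cells <- bad
    list(matrix = mat, truth = truth)
  })
}

# The 10 planted QC violators. Uses the RNG stream of the caller (make_counts
# runs inside with_seed). Boundary cells sit exactly on the strict cutoffs.
plant_bad_cells <- function(truth) {
  g <- truth$n_genes
  genes <- truth$gene_names
  mito <- genes %in% truth$mito_genes
  mu <- condition_mu(truth, truth$clusters[1], truth$samples[1])
  # probabilities with the mito block pinned at the target fraction
  p <- mu / sum(mu)
  p_nm <- p; p_nm[mito] <- 0; p_nm <- p_nm / sum(p_nm)
  p_m <- p; p_m[!mito] <- 0; p_m <- p_m / sum(p_m)
  f0 <- truth$mito_fraction_target

  cell_with_total <- function(total, mito_fraction = f0) {
    m_tot <- round(total * mito_fraction)
    v <- drop(rmultinom(1, total - m_tot, p_nm)) +
      drop(rmultinom(1, m_tot, p_m))
    v
  }
  cell_with_genes <- function(k, total = 9000) {
    # exactly k detected genes: give each chosen gene one count, spread the rest
    n_mito_pick <- min(length(truth$mito_genes), max(5L, round(0.01 * k)))
    picked <- c(sample(which(mito), n_mito_pick),
                sample(which(!mito), k - n_mito_pick))
    pp <- p[picked]
    # weight the mito picks so the mito fraction lands near the target
    pp[seq_len(n_mito_pick)] <- sum(pp[-seq_len(n_mito_pick)]) * f0 / (1 - f0) /
      n_mito_pick
    pp <- pp / sum(pp)
    v <- numeric(g)
    v[picked] <- 1 + drop(rmultinom(1, total - k, pp))
    v
  }
  cell_with_mito <- function(fraction, total = 10000) {
    m_tot <- round(total * fraction)
    v <- drop(rmultinom(1, total - m_tot, p_nm)) +
      drop(rmultinom(1, m_tot, p_m))
    v
  }

  spec <- list(
    list(name = "BAD_counts_3000", rule = "counts", v = cell_with_total(3000)),
    list(name = "BAD_counts_5000", rule = "counts", v = cell_with_total(5000)),
    list(name = "BAD_counts_6000", rule = "counts", v = cell_with_total(6000)),
    list(name = "BAD_genes_1000", rule = "genes", v = cell_with_genes(1000)),
    list(name = "BAD_genes_2000", rule = "genes", v = cell_with_genes(2000)),
    list(name = "BAD_genes_2600", rule = "genes", v = cell_with_genes(2600)),
    list(name = "BAD_mito_0.01", rule = "mito_low", v = cell_with_mito(0.01)),
    list(name = "BAD_mito_0.03", rule = "mito_low", v = cell_with_mito(0.03)),
    list(name = "BAD_mito_0.11", rule = "mito_high", v = cell_with_mito(0.11)),
    list(name = "BAD_mito_0.20", rule = "mito_high", v = cell_with_mito(0.20))
  )
  counts <- vapply(spec, function(s) s$v, numeric(g))
  colnames(counts) <- vapply(spec, `[[`, character(1), "name")
  rownames(counts) <- genes
  list(counts = counts,
       table = data.frame(cell = colnames(counts),
                          rule = vapply(spec, `[[`, character(1), "rule")))
}

#' Genes-by-cells count matrix container
#'
#' @param counts integer matrix or sparse Matrix, genes x cells, with
#'   dimnames.
#' @param mito logical per-gene mitochondrial flag.
#' @param sample per-cell sample label (e.g. WT / HD).
#' @param cluster optional per-cell lineage label.
#' @param covariates optional data.frame of per-cell scalar covariates
#'   (first column `cell`).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, mito, sample = NULL, cluster = NULL,
                         covariates = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_config("counts must carry gene and cell names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop_config("gene and cell names must be unique")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop_config("counts must be non-negative integers")
  }
  stopifnot(length(mito) == nrow(counts))
  n <- ncol(counts)
  structure(list(
    counts = counts,
    gene_names = rownames(counts), cell_names = colnames(counts),
    mito = setNames(as.logical(mito), rownames(counts)),
    sample = if (is.null(sample)) rep(NA_character_, n) else {
      stopifnot(length(sample) == n); as.character(sample)
    },
    cluster = if (is.null(cluster)) rep(NA_character_, n) else {
      stopifnot(length(cluster) == n); as.character(cluster)
    },
    covariates = covariates
  ), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      sum(x$mito), "mito genes; samples:",
      paste(unique(x$sample), collapse = ", "), "\n")
  invisible(x)
}

#' Subset the cells of a count matrix
#'
#' @param x a [count_matrix()].
#' @param cells cell names or logical/integer index.
#' @return a [count_matrix()] with the selected cells.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "count_matrix"))
  idx <- if (is.character(cells)) match(cells, x$cell_names) else {
    seq_len(ncol(x$counts))[cells]
  }
  if (anyNA(idx)) stop_config("unknown cell names")
  count_matrix(x$counts[, idx, drop = FALSE], mito = x$mito,
               sample = x$sample[idx], cluster = x$cluster[idx],
               covariates = if (!is.null(x$covariates)) {
                 x$covariates[idx, , drop = FALSE]
               })
}
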