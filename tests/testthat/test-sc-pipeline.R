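make_small_matrix <- function(counts, mito_prefix = "MT-") {
  count_matrix(counts, mito = startsWith(rownames(counts), mito_prefix))
}

test_that("QC filtering applies the strict cutoffs exactly", {
  genes <- c(sprintf("G%03d", 1:8), "MT-1", "MT-2")
  mk <- function(total, n_genes_detected, mito_frac) {
    v <- numeric(10)
    m <- round(total * mito_frac)
    v[9] <- m
    rest <- total - m
    k <- n_genes_detected - 1
    v[1:k] <- c(rep(1, k - 1), rest - (k - 1))
    v
  }
  counts <- cbind(
    pass = mk(8000, 8, 0.05),
    low_counts = mk(5000, 8, 0.05),
    edge_counts = mk(6001, 8, 0.05),  # 6001 > 6000 passes
    at_counts = mk(6000, 8, 0.05),    # exactly 6000 fails
    edge_mito = mk(8000, 8, 0.03)     # exactly 0.03 fails (strict)
  )
  rownames(counts) <- genes
  x <- make_small_matrix(counts)
  f <- qc_filter(x, min_counts = 6000, min_genes = 5,
                 mito_low = 0.03, mito_high = 0.11)
  expect_equal(f$qc$pass,
               c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(f$qc$failed_rules[f$qc$cell == "low_counts"], "counts")
  expect_equal(f$qc$failed_rules[f$qc$cell == "at_counts"], "counts")
  expect_equal(f$qc$failed_rules[f$qc$cell == "edge_mito"], "mito_low")
  # idempotence
  f2 <- qc_filter(f$matrix, min_counts = 6000, min_genes = 5,
                  mito_low = 0.03, mito_high = 0.11)
  expect_true(all(f2$qc$pass))
  expect_equal(f2$matrix$cell_names, f$matrix$cell_names)
})

test_that("QC requires flagged mitochondrial genes", {
  counts <- matrix(5, 4, 3,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  x <- count_matrix(counts, mito = rep(FALSE, 4))
  expect_error(qc_filter(x), "mitochondrial")
})

test_that("exactly the planted violators are removed from a synthetic matrix", {
  tr <- counts_truth(seed = 14, plant_bad_cells = TRUE,
                     n_cells_per_cluster = c(NE = 40, NC = 30, E = 30))
  mc <- make_counts(tr)
  f <- qc_filter(mc$matrix)
  removed <- f$qc$cell[!f$qc$pass]
  expect_setequal(removed, mc$truth$planted_bad_cells$cell)
})

test_that("log10 library-size normalization matches the closed form", {
  counts <- matrix(c(0, 9, 1, 0,
                     1, 9, 0, 9990), nrow = 4,
                   dimnames = list(paste0("g", 1:4), c("a", "b")))
  # cell a total = 10; cell b total = 10000 = scale_total
  norm <- normalize_log(counts, scale_total = 1e4)
  expect_equal(norm["g1", "a"], 0)                 # zero count -> 0
  expect_equal(norm["g4", "b"], log10(1 + 9990))
  expect_equal(norm["g2", "b"], log10(10))         # count 9, total = scale -> 1
  expect_equal(norm["g2", "b"], 1)

  # brute-force per-entry oracle on a random matrix
  set.seed(5)
  m <- matrix(rpois(60, 4), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  got <- normalize_log(m, scale_total = 500)
  for (j in 1:10) {
    for (i in 1:6) {
      expect_equal(got[i, j], log10(1 + m[i, j] * 500 / sum(m[, j])))
    }
  }
  # monotone in count within a cell
  o <- order(m[, 1])
  expect_true(all(diff(got[o, 1]) >= 0))

  # zero-total cells are flagged and zeroed
  m0 <- m; m0[, 2] <- 0
  expect_warning(g0 <- normalize_log(m0), "zero total")
  expect_true(all(g0[, 2] == 0))
  expect_equal(attr(g0, "zero_total_cells"), "c2")
})

test_that("covariate regression removes planted effects and nothing else", {
  set.seed(8)
  ncell <- 200
  cc <- rnorm(ncell)
  # gene 1: pure covariate effect; gene 2: orthogonal noise; gene 3: exact fit
  g1 <- 5 + 1.5 * cc + rnorm(ncell, sd = 0.1)
  g2 <- 3 + unname(residuals(lm(rnorm(ncell) ~ cc)))  # orthogonal to (1, cc)
  g3 <- 2 * cc
  expr <- rbind(g1 = g1, g2 = g2, g3 = g3)
  res <- regress_covariates(expr, cbind(cc = cc))
  expect_lt(abs(cor(res["g1", ], cc)), 1e-8)
  expect_equal(mean(res["g1", ]), mean(g1))
  expect_equal(res["g2", ], g2, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res["g3", ], rep(mean(g3), ncell), tolerance = 1e-8,
               ignore_attr = TRUE)

  # collinear covariates are dropped with a warning
  expect_warning(regress_covariates(expr, cbind(a = cc, b = 2 * cc)),
                 "collinear")
  expect_error(regress_covariates(expr, cbind(a = rep(1, ncell))), "distinct")
})

test_that("lineage scoring labels marker-pure and ambiguous cells correctly", {
  sets <- list(NE = c("PAX6", "SOX1"), NC = c("SOX10", "FOXD3"),
               E = c("KRT18", "TFAP2A"))
  genes <- c(unlist(sets), sprintf("G%03d", 1:50))
  expr <- matrix(0, length(genes), 3,
                 dimnames = list(genes, c("ne_cell", "zero_cell", "nc_cell")))
  expr[c("PAX6", "SOX1"), "ne_cell"] <- 3
  expr[c("SOX10", "FOXD3"), "nc_cell"] <- 3
  sl <- score_lineage(expr, sets, seed = 2)
  expect_equal(unname(sl$labels["ne_cell"]), "NE")
  expect_equal(unname(sl$labels["nc_cell"]), "NC")
  expect_true(is.na(sl$labels["zero_cell"]))
  suppressWarnings(
    expect_error(score_lineage(expr, list(NE = "PAX6", XX = "NOPE")),
                 "no marker"))
})

test_that("synthetic three-cluster matrices are annotated accurately", {
  tr <- counts_truth(seed = 25, n_genes = 1500,
                     n_cells_per_cluster = c(NE = 80, NC = 80, E = 80),
                     samples = "WT")
  mc <- make_counts(tr)
  expr <- normalize_log(mc$matrix)
  sl <- score_lineage(expr, default_marker_genes(), seed = 3)
  acc <- mean(!is.na(sl$labels) & sl$labels == mc$matrix$cluster)
  expect_gte(acc, 0.95)
})

test_that("hurdle test flags untestable genes and is symmetric in groups", {
  set.seed(31)
  ng <- 40
  counts <- matrix(rnbinom(ng * 80, mu = 3, size = 2), ng, 80,
                   dimnames = list(sprintf("g%02d", 1:ng), sprintf("c%02d", 1:80)))
  counts[1, ] <- 0                      # all-zero gene
  counts[2, ] <- c(5, 5, rep(0, 78))    # detected in 2 < 3 cells
  expr <- normalize_log(counts)
  de_ab <- hurdle_de(expr, 1:40, 41:80)
  expect_false(de_ab$testable[1])
  expect_equal(de_ab$p_hurdle[1], 1)
  expect_false(de_ab$testable[2])
  de_ba <- hurdle_de(expr, 41:80, 1:40)
  expect_equal(de_ba$log_fc, -de_ab$log_fc)
  expect_equal(de_ba$p_hurdle, de_ab$p_hurdle, tolerance = 1e-6)
  expect_error(hurdle_de(expr, integer(0), 1:10), "non-empty")
  expect_error(hurdle_de(expr, 1:10, 5:20), "overlap")
})

test_that("a strong planted shift is detected by the hurdle test", {
  set.seed(33)
  ng <- 200
  mu <- rep(2, ng)
  a <- matrix(rnbinom(ng * 100, mu = c(rep(8, 20), mu[-(1:20)]), size = 2),
              ng, 100)
  b <- matrix(rnbinom(ng * 100, mu = mu, size = 2), ng, 100)
  m <- cbind(a, b)
  dimnames(m) <- list(sprintf("g%03d", 1:ng), sprintf("c%03d", 1:200))
  de <- hurdle_de(normalize_log(m), 1:100, 101:200)
  expect_gt(mean(de$fdr[1:20] < 0.05), 0.9)
  expect_true(all(de$log_fc[1:20] > 0))
})

test_that("gene-set enrichment p-values are +1-corrected and deterministic", {
  set.seed(44)
  ng <- 300
  m <- matrix(rnbinom(ng * 120, mu = 3, size = 2), ng, 120,
              dimnames = list(sprintf("g%03d", 1:ng), sprintf("c%03d", 1:120)))
  expr <- normalize_log(m)
  de <- hurdle_de(expr, 1:60, 61:120)
  r1 <- gene_set_enrichment(de, sprintf("g%03d", 1:30), n_perm = 999, seed = 6)
  r2 <- gene_set_enrichment(de, sprintf("g%03d", 1:30), n_perm = 999, seed = 6)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gt(r1$p_perm, 0)
  expect_gte(r1$p_perm, 1 / 1000)

  # degenerate set = all genes: score is the global mean, p non-extreme
  rall <- gene_set_enrichment(de, rownames(expr), n_perm = 999, seed = 7)
  z <- neurquant:::de_zscores(de)
  expect_equal(rall$score, mean(z[!is.na(z)]))
  expect_gt(rall$p_perm, 0.1)
  expect_lt(rall$p_perm, 0.9)

  expect_warning(
    gene_set_enrichment(de, sprintf("g%03d", 1:3), n_perm = 999, seed = 8),
    "testable genes")
})

test_that("count matrices round-trip through MTX and dense TSV", {
  tr <- counts_truth(seed = 55, n_genes = 700,
                     n_cells_per_cluster = c(NE = 15, NC = 15, E = 15))
  mc <- make_counts(tr)
  d <- withr::local_tempdir()
  write_counts_mtx(mc$matrix, d)
  x2 <- read_counts_mtx(d)
  expect_true(all(x2$counts == mc$matrix$counts))
  expect_equal(x2$gene_names, mc$matrix$gene_names)
  expect_equal(x2$sample, mc$matrix$sample)
  expect_equal(x2$mito, mc$matrix$mito)
  expect_equal(x2$covariates$cc_score, mc$matrix$covariates$cc_score)

  f <- file.path(d, "dense.tsv")
  write_counts_tsv(mc$matrix, f)
  x3 <- read_counts_tsv(f)
  expect_true(all(x3$counts == mc$matrix$counts))
  expect_equal(sum(x3$mito), length(tr$mito_genes))
})

test_that("gene sets round-trip through GMT", {
  sets <- list(alpha = c("PAX6", "SOX1"), beta = sprintf("G%02d", 1:5))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  got <- read_gmt(f)
  expect_equal(got, sets)
})
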