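#!/usr/bin/env Rscript
# Simulate the single-cell arm's raw material: a WT/HD gene-by-cell count
# matrix with three ectodermal lineages (NE, NC, E), lineage marker genes, a
# 364-gene "YAP-target" set upshifted 2-fold in the NE cluster of HD,
# mitochondrial genes at a ~6% count fraction, a synthetic cell-cycle score,
# and 10 planted low-quality cells sitting on the QC rule boundaries.
#
# Outputs: results/sc_counts/ (MTX triplet), results/yap_targets.gmt

suppressMessages(library(neurquant))
dir.create("results", showWarnings = FALSE)
seed <- 20260927

truth <- counts_truth(
  n_genes = 4000,
  n_cells_per_cluster = c(NE = 300, NC = 200, E = 300),
  samples = c("WT", "HD"),
  planted_set_size = 364,
  set_shift = data.frame(cluster = "NE", sample = "HD", log2_fc = 1),
  plant_bad_cells = TRUE,
  seed = seed)
sim <- make_counts(truth)

write_counts_mtx(sim$matrix, "results/sc_counts")
write_gmt(list(YAP_TARGETS_SYNTHETIC = truth$planted_set),
          "results/yap_targets.gmt",
          description = "synthetic stand-in for a curated YAP-target list")

qc <- cell_qc_metrics(sim$matrix)
message("simulated ", nrow(sim$matrix$counts), " genes x ",
        ncol(sim$matrix$counts), " cells (",
        sum(sim$matrix$sample == "WT"), " WT, ",
        sum(sim$matrix$sample == "HD"), " HD; 10 planted QC violators)")
message(sprintf("typical cell: %d counts, %d genes, %.1f%% mito",
                round(median(qc$total_counts)),
                round(median(qc$detected_genes)),
                100 * median(qc$mito_fraction)))
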