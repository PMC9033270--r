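#!/usr/bin/env Rscript
# Simulate the imaging arm's raw material: a micropattern array of 500-µm
# colonies (for detection/cropping) and two cohorts of single colonies --
# "WT-like" (central PAX6-like domain covering 25% of the colony, SOX10-like
# ring at 175 µm) and "HD-like" (expanded central domain at 40%, attenuated
# and outward-shifted ring) -- with Poisson shot noise and full ground truth.
#
# Outputs (results/):
#   colony_field.tif(.json)  one 2x2 array field, 16-bit multi-channel TIFF
#   colony_truths.json       planted geometry of every simulated colony
# Scratch-free: single-colony cohorts are re-derived by seed in 02.

suppressMessages(library(neurquant))
dir.create("results", showWarnings = FALSE)

seed <- 20260927

template <- colony_truth(seed = seed, n_nuclei = 100,
                         confluent_dapi_level = 40,
                         noise = list(type = "poisson"))
arr <- make_colony_array(4, template, jitter_um = 5, seed = seed)
write_stack(mc_stack(lapply(arr$channels, round), pixel_size_um = 2),
            "results/colony_field.tif")

truth_summary <- lapply(arr$truths, function(tr) {
  list(center_y = tr$center[["y"]], center_x = tr$center[["x"]],
       colony_radius_um = tr$colony_radius_um,
       central_disk_radius_um = tr$central_disk_radius_um,
       ring_center_radius_um = tr$ring_center_radius_um,
       n_nuclei = nrow(tr$nuclei), seed = tr$seed)
})
jsonlite::write_json(truth_summary, "results/colony_truths.json",
                     auto_unbox = TRUE, pretty = TRUE)

message("simulated a 2x2 array of 500-um colonies (",
        nrow(arr$channels$DAPI), "x", ncol(arr$channels$DAPI),
        " px field) -> results/colony_field.tif")
message("cohort parameters: WT-like central fraction 0.25, ring 175 um @100; ",
        "HD-like central fraction 0.40, ring 205 um @40 (re-derived by seed in 02)")
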