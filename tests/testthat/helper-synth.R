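# Small fixture builders shared across test files.

# A minimal colony_image built directly from matrices (center at the middle).
tiny_colony <- function(channels, radius_px = NULL, pixel_size_um = 1,
                        colony_id = "tiny") {
  d <- dim(channels[[1]])
  ctr <- c(y = (d[1] + 1) / 2, x = (d[2] + 1) / 2)
  colony_image(channels, center = ctr,
               radius_px = radius_px %||% ((min(d) - 1) / 2),
               pixel_size_um = pixel_size_um, colony_id = colony_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force radial binning oracle: assign each pixel by its exact radius.
brute_force_profile <- function(mat, cy, cx, bw, pixel_size_um, max_r) {
  edges <- seq(0, max_r, by = bw)
  if (edges[length(edges)] < max_r) edges <- c(edges, max_r)
  nb <- length(edges) - 1
  s <- numeric(nb); n <- integer(nb)
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      r <- sqrt((i - cy)^2 + (j - cx)^2) * pixel_size_um
      for (b in seq_len(nb)) {
        if (r >= edges[b] && r < edges[b + 1]) {
          s[b] <- s[b] + mat[i, j]; n[b] <- n[b] + 1L
          break
        }
      }
    }
  }
  list(mean = ifelse(n > 0, s / pmax(n, 1), NA_real_), n = n)
}

# Gaussian-noise truth used by several segmentation tests: 50 nuclei at >= 3
# sigma separation, peak 100, noise SD 20 (SNR 5).
segmentation_truth <- function(seed, n_nuclei = 50) {
  colony_truth(seed = seed, n_nuclei = n_nuclei,
               nuclear_channels = c(DAPI = 100, YAP = 80),
               nuclear_level_cv = 0.1,
               noise = list(type = "gaussian", sd = 20))
}

# Expected per-gene NB mean for a single-cluster, no-shift counts truth.
condition_mu_for_test <- function(tr) {
  mu <- tr$base_mu
  mu[tr$marker_genes$NE] <- mu[tr$marker_genes$NE] * tr$marker_fold
  mu
}
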