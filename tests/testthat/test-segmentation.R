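test_that("pixel classification separates a clean bimodal image exactly", {
  tr <- colony_truth(seed = 4, n_nuclei = 25, nucleus_shape = "disk",
                     nuclear_level_cv = 0, background = 10,
                     noise = list(type = "none"),
                     central_channel = NULL, ring_channel = NULL)
  img <- make_colony_image(tr)$image
  mask <- classify_nucleus_pixels(img$channels$DAPI, fill_holes = FALSE)
  expect_equal(matrix(as.logical(mask), nrow(mask), ncol(mask)),
               truth_masks(tr)$nuclei)
})

test_that("a constant image yields an empty mask", {
  m <- classify_nucleus_pixels(matrix(7, 30, 30))
  expect_false(any(m))
})

test_that("trained classifier reproduces a clean separation and validates input", {
  expect_error(classify_nucleus_pixels(matrix(0, 5, 5), method = "trained"),
               "classifier")
  tr <- colony_truth(seed = 8, n_nuclei = 20, nucleus_shape = "disk",
                     nuclear_level_cv = 0, background = 10,
                     noise = list(type = "gaussian", sd = 5),
                     central_channel = NULL, ring_channel = NULL)
  img <- make_colony_image(tr)$image
  truth <- truth_masks(tr)$nuclei
  clf <- train_pixel_classifier(list(img$channels$DAPI),
                                list(ifelse(truth, 1, 0)))
  mask <- classify_nucleus_pixels(img$channels$DAPI, method = "trained",
                                  classifier = clf, min_area = 5)
  jacc <- sum(mask & truth) / sum(mask | truth)
  expect_gt(jacc, 0.8)
})

test_that("noisy-colony mask clears the Jaccard floor against truth", {
  tr <- colony_truth(seed = 12, n_nuclei = 50, nucleus_shape = "disk",
                     nuclear_level_cv = 0.1, background = 10,
                     noise = list(type = "gaussian", sd = 20),
                     central_channel = NULL, ring_channel = NULL)
  img <- make_colony_image(tr)$image
  mask <- classify_nucleus_pixels(img$channels$DAPI, min_area = 8,
                                  pre_smooth_sigma = 1)
  truth <- truth_masks(tr)$nuclei
  jacc <- sum(mask & truth) / sum(mask | truth)
  expect_gt(jacc, 0.8)
})

test_that("seed detection finds isolated blobs and respects the threshold", {
  img <- matrix(0, 40, 40)
  blob <- function(cy, cx, s = 2.5, lv = 100) {
    for (i in 1:40) for (j in 1:40) {
      d2 <- (i - cy)^2 + (j - cx)^2
      if (d2 <= (3 * s)^2) img[i, j] <<- img[i, j] + lv * exp(-d2 / (2 * s^2))
    }
  }
  blob(12, 12)
  s1 <- detect_seeds(img, filter_radius_px = 3, threshold = 10)
  expect_equal(nrow(s1), 1)
  expect_lt(sqrt((s1$y - 12)^2 + (s1$x - 12)^2), 2)

  s0 <- detect_seeds(img, filter_radius_px = 3, threshold = max(img) * 2)
  expect_equal(nrow(s0), 0)

  blob(12, 24)  # second blob 12 px = 4 * radius away
  s2 <- detect_seeds(img, filter_radius_px = 3, threshold = 10)
  expect_equal(nrow(s2), 2)
})

test_that("watershed respects components, seeds and the intensity valley", {
  # two disjoint blobs: labels equal the per-blob components
  img <- matrix(0, 30, 30)
  img[5:10, 5:10] <- 100
  img[20:25, 20:25] <- 100
  mask <- img > 50
  seeds <- data.frame(y = c(7, 22), x = c(7, 22))
  lab <- watershed_segment(mask, seeds, img, smooth_sigma = 0)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
  expect_true(all(lab[5:10, 5:10] == 1))
  expect_true(all(lab[20:25, 20:25] == 2))
  expect_true(all((lab > 0) == mask))

  # one seed in a two-blob component claims the whole component
  lab1 <- watershed_segment(mask, seeds[1, , drop = FALSE], img,
                            smooth_sigma = 0)
  expect_true(all(lab1[5:10, 5:10] == 1))

  # touching blobs: the boundary sits on the 1-D intensity valley
  prof <- 100 * exp(-((1:20) - 6)^2 / 8) + 80 * exp(-((1:20) - 15)^2 / 8)
  img2 <- matrix(rep(prof, each = 20), 20, 20)
  mask2 <- matrix(TRUE, 20, 20)
  seeds2 <- data.frame(y = c(10, 10), x = c(6, 15))
  lab2 <- watershed_segment(mask2, seeds2, img2, smooth_sigma = 0)
  valley <- which.min(prof[6:15]) + 5      # independent 1-D oracle
  for (i in 1:20) {
    expect_true(all(lab2[i, 1:(valley - 1)] == 1))
    expect_true(all(lab2[i, (valley + 1):20] == 2))
  }

  # seeds outside the mask are dropped with a warning
  expect_warning(
    lab3 <- watershed_segment(mask, data.frame(y = c(7, 2), x = c(7, 28)),
                              img, smooth_sigma = 0),
    "dropped")
  expect_equal(max(lab3), 1)

  # empty mask -> empty labelling
  lab4 <- watershed_segment(matrix(FALSE, 5, 5), seeds,
                            matrix(0, 5, 5))
  expect_true(all(lab4 == 0))
})

test_that("relabelling seeds permutes labels but not geometry", {
  tr <- segmentation_truth(seed = 31, n_nuclei = 25)
  img <- make_colony_image(tr)$image
  seg <- segment_colony(img)
  rev_seeds <- seg$seeds[rev(seq_len(nrow(seg$seeds))), ]
  lab_rev <- watershed_segment(seg$mask, rev_seeds, img$channels$DAPI)
  k <- nrow(seg$seeds)
  expect_identical(lab_rev > 0, seg$labels > 0)
  # region of seed i under one ordering equals region of seed k+1-i under the other
  for (i in seq_len(k)) {
    expect_identical(which(seg$labels == i), which(lab_rev == k + 1 - i))
  }
})

test_that("nucleus measurements report medians and scale with intensity", {
  ch <- matrix(0, 9, 9)
  lab <- matrix(0L, 9, 9)
  lab[2:4, 2:4] <- 1L; ch[2:4, 2:4] <- 7
  lab[6:8, 6:8] <- 2L; ch[6:8, 6:8] <- c(3, 3, 9)  # recycled triplet
  colony <- tiny_colony(list(DAPI = ch, YAP = 2 * ch), radius_px = 4)
  rec <- measure_nuclei(lab, colony)
  expect_equal(rec$DAPI, c(7, 3))
  expect_equal(rec$area_px, c(9, 9))
  # intensity equivariance: scaling a channel scales its medians
  expect_equal(rec$YAP, 2 * rec$DAPI)
  colony2 <- tiny_colony(list(DAPI = ch, YAP = 10 * ch), radius_px = 4)
  rec2 <- measure_nuclei(lab, colony2)
  expect_equal(rec2$YAP, 10 * rec$DAPI)
  expect_equal(rec2$DAPI, rec$DAPI)
})

test_that("noise-free planted nuclei are recovered with exact medians", {
  tr <- colony_truth(seed = 19, n_nuclei = 50,
                     nuclear_channels = c(DAPI = 100, YAP = 80),
                     background = 0, noise = list(type = "none"),
                     central_channel = NULL, ring_channel = NULL)
  img <- make_colony_image(tr)$image
  seg <- segment_colony(img)
  m <- match_points(tr$nuclei[, c("y", "x")], seg$records[, c("y", "x")],
                    max_dist = 3)
  expect_equal(nrow(m), 50)
  expect_equal(seg$records$YAP[m$found_idx], tr$nuclei$YAP[m$truth_idx],
               tolerance = 1e-8)
  # label conservation: labels <= seeds; union inside mask
  expect_lte(max(seg$labels), nrow(seg$seeds))
  expect_true(all(seg$mask[seg$labels > 0]))
})
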