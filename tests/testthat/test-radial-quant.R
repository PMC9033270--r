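test_that("radial profile is exact on uniform disks and annuli", {
  # uniform disk: every interior bin mean = c
  n <- 61
  r <- sqrt(outer((1:n - 31)^2, (1:n - 31)^2, `+`))
  disk <- ifelse(r <= 28, 5, 0)
  colony <- tiny_colony(list(PAX6 = disk, DAPI = disk), radius_px = 28)
  p <- radial_profile(colony, "PAX6", bin_width_um = 4,
                      center = c(y = 31, x = 31))
  expect_true(all(p$mean[p$bin_hi_um <= 28] == 5))

  # annulus: bins wholly inside the inner radius average 0
  ann <- ifelse(r >= 15 & r <= 25, 1, 0)
  colony2 <- tiny_colony(list(SOX10 = ann, DAPI = disk), radius_px = 28)
  p2 <- radial_profile(colony2, "SOX10", bin_width_um = 3,
                       center = c(y = 31, x = 31))
  expect_true(all(p2$mean[p2$bin_hi_um <= 15] == 0))
  expect_error(radial_profile(colony2, "KRT18"), "not present")
})

test_that("radial profile equals the brute-force per-pixel oracle", {
  set.seed(23)
  m <- matrix(runif(41 * 41), 41, 41)
  colony <- tiny_colony(list(DAPI = m), radius_px = 19, pixel_size_um = 1.5)
  ctr <- c(y = 21.3, x = 20.6)
  p <- radial_profile(colony, "DAPI", bin_width_um = 4, center = ctr)
  bf <- brute_force_profile(m, 21.3, 20.6, 4, 1.5, 19 * 1.5)
  expect_equal(p$mean, bf$mean)
  expect_equal(p$n, bf$n)
})

test_that("radial profile is rotation invariant and conserves intensity", {
  set.seed(3)
  m <- matrix(rpois(51 * 51, 20), 51, 51)
  ctr <- c(y = 26, x = 26)
  colony <- tiny_colony(list(DAPI = m), radius_px = 24)
  rot <- t(m)[, rev(seq_len(51))]  # 90-degree rotation about the center
  colony_rot <- tiny_colony(list(DAPI = rot), radius_px = 24)
  p1 <- radial_profile(colony, "DAPI", center = ctr)
  p2 <- radial_profile(colony_rot, "DAPI", center = ctr)
  expect_identical(p1$mean, p2$mean)
  expect_identical(p1$n, p2$n)

  # conservation: sum(mean * n) equals the summed intensity inside the disk
  r <- sqrt(outer((1:51 - 26)^2, (1:51 - 26)^2, `+`))
  expect_equal(sum(p1$mean * p1$n, na.rm = TRUE), sum(m[r < 24]))
})

test_that("nucleus-source profiles bin per-nucleus medians by radius", {
  rec <- data.frame(colony_id = "c", label = 1:4,
                    radial_distance_um = c(2, 7, 12, 13),
                    YAP = c(10, 20, 30, 40))
  colony <- tiny_colony(list(YAP = matrix(0, 21, 21)), radius_px = 10,
                        pixel_size_um = 2)
  p <- radial_profile(colony, "YAP", bin_width_um = 5, source = "nuclei",
                      records = rec, center = c(y = 11, x = 11))
  expect_equal(p$mean, c(10, 20, c(30 + 40) / 2, NA))
  expect_equal(p$n, c(1, 1, 2, 0))
})

test_that("profile aggregation averages across colonies", {
  p <- profile_from_values(seq(0, 20, 5), c(1, 2, 3, 4), n = rep(10, 4),
                           radius_um = 20)
  agg <- aggregate_profiles(list(p, p, p))
  expect_equal(agg$mean, c(1, 2, 3, 4))
  expect_equal(agg$sd, rep(0, 4))
  expect_equal(agg$n_colonies, rep(3, 4))

  p0 <- profile_from_values(seq(0, 20, 5), c(0, 0, 0, 0), n = rep(10, 4),
                            radius_um = 20)
  p2 <- profile_from_values(seq(0, 20, 5), c(2, 2, 2, 2), n = rep(10, 4),
                            radius_um = 20)
  agg2 <- aggregate_profiles(list(p0, p2))
  expect_equal(agg2$mean, rep(1, 4))
  expect_equal(agg2$sd, rep(sd(c(0, 2)), 4))
})

test_that("aggregated synthetic ring colonies track the analytic profile", {
  truths <- lapply(1:9, function(s) {
    colony_truth(seed = 100 + s, n_nuclei = 0, background = 5,
                 central_channel = NULL, noise = list(type = "poisson"))
  })
  profs <- lapply(truths, function(tr) {
    img <- make_colony_image(tr)$image
    radial_profile(img, "SOX10", center = tr$center)
  })
  agg <- aggregate_profiles(profs)
  analytic <- 5 + 100 * exp(-(agg$frac_mid * 250 - 175)^2 / (2 * 15^2))
  # Monte-Carlo bound: Poisson noise averaged over bins and colonies
  expect_lt(max(abs(agg$mean - analytic)), 3)
})

test_that("edge averages weight the outer bins by pixel counts", {
  p <- profile_from_values(seq(0, 100, 10), rep(4, 10), n = rep(7, 10),
                           radius_um = 100)
  expect_equal(edge_average(p, 0.1), 4)
  expect_equal(edge_average(p, 0.3), 4)

  means <- c(rep(0, 9), 8)
  p2 <- profile_from_values(seq(0, 100, 10), means, n = rep(5, 10),
                            radius_um = 100)
  expect_equal(edge_average(p2, 0.1), 8)

  # brute-force check on a synthetic ring colony
  tr <- colony_truth(seed = 41, n_nuclei = 0, background = 0,
                     central_channel = NULL, noise = list(type = "none"))
  img <- make_colony_image(tr)$image
  p3 <- radial_profile(img, "SOX10", center = tr$center)
  got <- edge_average(p3, 0.1)
  r <- sqrt(outer((seq_len(tr$canvas_px) - tr$center["y"])^2,
                  (seq_len(tr$canvas_px) - tr$center["x"])^2, `+`)) * 2
  sel <- r >= 0.9 * 250 & r < 250
  # same pixels, binned: agree to well under the ring's bin-scale variation
  expect_lt(abs(got - mean(img$channels$SOX10[sel])), 0.5)
})

test_that("half-max radius interpolates linearly and flags flat profiles", {
  edges <- seq(0, 150, 5)
  mids <- edges[-1] - 2.5
  y <- pmin(pmax((mids - 100) / 25, 0), 1)
  p <- profile_from_values(edges, y, radius_um = 150)
  expect_equal(as.numeric(half_max_radius(p)), 112.5)

  flat <- profile_from_values(edges, rep(3, 30), radius_um = 150)
  r <- half_max_radius(flat)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "contrast|domain")

  too_few <- profile_from_values(seq(0, 10, 5), c(1, 2), radius_um = 10)
  expect_true(is.na(half_max_radius(too_few)))
})

test_that("half-max matches the analytic Gaussian-annulus crossing", {
  bw <- 5
  edges <- seq(0, 250, bw)
  mids <- edges[-1] - bw / 2
  y <- exp(-(mids - 200)^2 / (2 * 20^2))
  p <- profile_from_values(edges, y, radius_um = 250)
  analytic <- 200 - 20 * sqrt(2 * log(2))
  expect_lt(abs(as.numeric(half_max_radius(p)) - analytic), bw / 2)
})

test_that("half-max radius grows with the planted ring radius", {
  vals <- vapply(c(150, 175, 200), function(rc) {
    tr <- colony_truth(seed = 55, n_nuclei = 0, background = 0,
                       central_channel = NULL, ring_center_radius_um = rc,
                       noise = list(type = "none"))
    img <- make_colony_image(tr)$image
    as.numeric(half_max_radius(radial_profile(img, "SOX10",
                                              center = tr$center)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # within ~half a bin of the analytic rising half-max (smoothing shifts < 1 um)
  expect_lt(max(abs(vals - (c(150, 175, 200) - 15 * sqrt(2 * log(2))))), 3)
})

test_that("marker area fractions recover planted disk geometry", {
  tr <- colony_truth(seed = 61, n_nuclei = 80, confluent_dapi_level = 50,
                     central_disk_radius_um = 125, noise = list(type = "none"),
                     background = 0)
  img <- make_colony_image(tr)$image
  f <- positive_area_fraction(img, "PAX6")
  expect_equal(f, 0.25, tolerance = 0.01)

  # marker everywhere positive
  img2 <- img
  img2$channels$PAX6 <- img$channels$DAPI  # positive wherever reference is
  expect_equal(positive_area_fraction(img2, "PAX6", threshold_method = 25), 1)

  cf <- central_domain_fraction(img, "PAX6", center = tr$center)
  expect_equal(cf, 0.25, tolerance = 0.01)
  # central fraction cannot exceed the overall positive fraction here
  expect_lte(cf, f + 0.005)
})

test_that("central-domain fraction excludes detached specks", {
  n <- 101
  r <- sqrt(outer((1:n - 51)^2, (1:n - 51)^2, `+`))
  mk <- ifelse(r <= 25, 100, 0)
  mk[5:7, 5:7] <- 100  # detached peripheral speck
  colony <- tiny_colony(list(PAX6 = mk, DAPI = ifelse(r <= 50, 50, 0)),
                        radius_px = 50)
  f <- central_domain_fraction(colony, "PAX6", center = c(y = 51, x = 51))
  expect_equal(f, 0.25, tolerance = 0.01)
  expect_lt(f, sum(mk > 50) / (pi * 50^2))  # the speck was excluded

  blank <- tiny_colony(list(PAX6 = matrix(0, 21, 21)), radius_px = 10)
  expect_equal(central_domain_fraction(blank, "PAX6",
                                       center = c(y = 11, x = 11)), 0)
})

test_that("planted noisy central-disk fractions are recovered", {
  fracs <- vapply(1:10, function(s) {
    tr <- colony_truth(seed = 300 + s, n_nuclei = 100,
                       central_disk_radius_um = 250 * sqrt(0.4),
                       noise = list(type = "poisson"))
    img <- make_colony_image(tr)$image
    central_domain_fraction(img, "PAX6")
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.4), 0.02)
})

test_that("nuclear signal normalization is scale invariant", {
  rec <- data.frame(colony_id = rep(c("a", "b"), each = 4),
                    DAPI = rep(c(50, 100), each = 4),
                    YAP = c(10, 20, 30, 40, 60, 70, 80, 90))
  nr <- normalize_nuclear_signal(rec, "YAP")
  expect_equal(nr$normalized[1:4], c(10, 20, 30, 40) / 50)
  expect_equal(nr$normalized[5:8], c(60, 70, 80, 90) / 100)
  # doubling exposure of both channels leaves the ratio unchanged
  rec2 <- rec; rec2$DAPI <- 2 * rec$DAPI; rec2$YAP <- 2 * rec$YAP
  expect_equal(normalize_nuclear_signal(rec2, "YAP")$normalized,
               nr$normalized)
  # z-score of constant signals is 0
  rec3 <- data.frame(colony_id = "a", DAPI = 50, YAP = rep(5, 6))
  expect_equal(normalize_nuclear_signal(rec3, "YAP",
                                        method = "per-colony-zscore")$normalized,
               rep(0, 6))
})

test_that("mitotic index counts thresholded pH3-positive nuclei", {
  rec <- data.frame(colony_id = "a", pH3 = c(rep(1, 95), rep(100, 5)))
  expect_equal(mitotic_index(rec, threshold = 50), 0.05)
  expect_equal(mitotic_index(rec, threshold = 1000), 0)
  expect_warning(mi <- mitotic_index(rec[0, ]), "no nuclei")
  expect_true(is.na(mi))
})

test_that("planted mitotic fractions are recovered from noisy colonies", {
  tr <- colony_truth(seed = 77, n_nuclei = 100, mitotic_fraction = 0.1,
                     noise = list(type = "gaussian", sd = 10),
                     central_channel = NULL, ring_channel = NULL)
  img <- make_colony_image(tr)$image
  seg <- segment_colony(img)
  mi <- mitotic_index(seg$records, threshold = 50)
  planted <- mean(tr$nuclei$mitotic)
  # binomial 95% interval around the planted fraction
  expect_lt(abs(mi - planted), 1.96 * sqrt(planted * (1 - planted) / 100) + 0.01)
})
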