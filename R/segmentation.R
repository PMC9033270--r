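#' Classify pixels into nucleus vs background
#'
#' Produces a binary nucleus mask from the DAPI channel. The default method is
#' Otsu thresholding; alternatively a trainable per-pixel classifier (logistic
#' regression on intensity, two Gaussian-smoothed intensities and gradient
#' magnitude, fitted by [train_pixel_classifier()]) can stand in for an
#' interactively trained tool. Holes are filled and objects below `min_area`
#' removed.
#'
#' @param dapi numeric matrix (DAPI channel).
#' @param method `"otsu"` (default) or `"trained"`.
#' @param classifier a model from [train_pixel_classifier()]; required for
#'   `method = "trained"`.
#' @param min_area remove connected components smaller than this (px); 0 keeps
#'   all.
#' @param fill_holes fill holes in the mask (default TRUE).
#' @param pre_smooth_sigma Gaussian sigma (px) applied before Otsu
#'   thresholding; 0 (default) thresholds the raw image. Smoothing suppresses
#'   shot/readout noise that otherwise frays mask boundaries.
#' @return logical matrix with attribute `provenance`.
#' @export
classify_nucleus_pixels <- function(dapi, method = c("otsu", "trained"),
                                    classifier = NULL, min_area = 0,
                                    fill_holes = TRUE, pre_smooth_sigma = 0) {
  method <- match.arg(method)
  if (method == "otsu") {
    work <- if (pre_smooth_sigma > 0) {
      as.matrix(EBImage::gblur(dapi, sigma = pre_smooth_sigma))
    } else dapi
    thr <- otsu_threshold(work)
    mask <- is.finite(thr) & work > thr
    prov <- list(method = "otsu", threshold = thr,
                 pre_smooth_sigma = pre_smooth_sigma)
  } else {
    if (is.null(classifier)) {
      stop_config("method = 'trained' requires a fitted classifier ",
                  "(see train_pixel_classifier)")
    }
    feats <- pixel_features(dapi)
    eta <- drop(cbind(1, feats) %*% classifier$coef)
    mask <- matrix(eta > 0, nrow(dapi), ncol(dapi))
    prov <- list(method = "trained", coef = classifier$coef)
  }
  mask <- matrix(as.logical(mask), nrow(dapi), ncol(dapi))
  if (fill_holes && any(mask)) {
    mask <- EBImage::fillHull(mask) > 0
  }
  if (min_area > 0 && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    keep <- which(tabulate(lab[lab > 0], max(lab)) >= min_area)
    mask <- matrix(lab %in% keep, nrow(dapi), ncol(dapi))
  }
  prov$min_area <- min_area
  attr(mask, "provenance") <- prov
  mask
}

# Per-pixel features: raw intensity, Gaussian-smoothed at 2 scales, gradient
# magnitude (central differences on the 1-px smoothed image).
pixel_features <- function(img, sigmas = c(1, 4)) {
  sm <- lapply(sigmas, function(s) EBImage::gblur(img, sigma = s))
  g <- sm[[1]]
  gy <- rbind(g[2, , drop = FALSE], g[-1, , drop = FALSE]) -
    rbind(g[1, , drop = FALSE], g[-nrow(g), , drop = FALSE])
  gx <- cbind(g[, 2, drop = FALSE], g[, -1, drop = FALSE]) -
    cbind(g[, 1, drop = FALSE], g[, -ncol(g), drop = FALSE])
  cbind(intensity = as.numeric(img),
        smooth1 = as.numeric(sm[[1]]),
        smooth2 = as.numeric(sm[[2]]),
        gradmag = as.numeric(sqrt(gy^2 + gx^2)))
}

#' Train the per-pixel nucleus classifier on labelled example images
#'
#' @param images list of numeric matrices.
#' @param labels list of matrices with 1 = nucleus, 0 = background, NA =
#'   unlabelled, matching `images` in shape.
#' @return classifier object (logistic-regression coefficients) for
#'   [classify_nucleus_pixels()].
#' @export
train_pixel_classifier <- function(images, labels) {
  stopifnot(length(images) == length(labels), length(images) >= 1)
  X <- NULL; y <- NULL
  for (i in seq_along(images)) {
    f <- pixel_features(images[[i]])
    l <- as.numeric(labels[[i]])
    keep <- !is.na(l)
    X <- rbind(X, f[keep, , drop = FALSE])
    y <- c(y, l[keep])
  }
  if (length(y) == 0 || length(unique(y)) < 2) {
    stop_config("labelled examples must contain both classes")
  }
  fit <- suppressWarnings(glm.fit(cbind(1, X), y, family = binomial()))
  structure(list(coef = coef(fit)), class = "pixel_classifier")
}

#' Detect nucleus seeds with a disk matched filter
#'
#' Convolves the image with a normalized disk kernel ("sphere filter" in 2-D)
#' and keeps local maxima of the response above `threshold`, enforcing a
#' minimum seed separation equal to the filter radius.
#'
#' @param dapi numeric matrix.
#' @param filter_radius_px disk radius in pixels (default: expected nucleus
#'   radius).
#' @param threshold response threshold; `NULL` (default) uses Otsu on the
#'   filter response. The thresholds the original procedure set by hand are
#'   exposed here as configuration.
#' @param min_separation_px minimum distance between retained seeds.
#' @return data.frame with `y`, `x`, `response`, plus attributes
#'   `filter_radius_px` and `threshold`.
#' @export
detect_seeds <- function(dapi, filter_radius_px, threshold = NULL,
                         min_separation_px = filter_radius_px) {
  stopifnot(filter_radius_px > 0)
  resp <- EBImage::filter2(dapi, disk_kernel(filter_radius_px),
                           boundary = "replicate")
  if (is.null(threshold)) threshold <- otsu_threshold(resp)
  brush_size <- 2L * floor(min_separation_px) + 1L
  local_max <- resp >= EBImage::dilate(resp, EBImage::makeBrush(brush_size, "disc"))
  cand <- which(local_max & resp > threshold)
  out <- data.frame(y = integer(0), x = integer(0), response = numeric(0))
  if (length(cand)) {
    ys <- (cand - 1L) %% nrow(dapi) + 1L
    xs <- (cand - 1L) %/% nrow(dapi) + 1L
    rs <- resp[cand]
    o <- order(-rs, ys, xs)
    ys <- ys[o]; xs <- xs[o]; rs <- rs[o]
    keep_y <- keep_x <- integer(0); keep_r <- numeric(0)
    for (i in seq_along(ys)) {
      if (length(keep_y) == 0 ||
          min((keep_y - ys[i])^2 + (keep_x - xs[i])^2) >= min_separation_px^2) {
        keep_y <- c(keep_y, ys[i]); keep_x <- c(keep_x, xs[i])
        keep_r <- c(keep_r, rs[i])
      }
    }
    out <- data.frame(y = keep_y, x = keep_x, response = keep_r)
  }
  attr(out, "filter_radius_px") <- filter_radius_px
  attr(out, "threshold") <- threshold
  out
}

#' Seeded watershed segmentation of the nucleus mask
#'
#' Floods the negated (optionally Gaussian-smoothed) DAPI intensity from the
#' seeds, constrained to the mask, so region boundaries fall on intensity
#' valleys between nuclei. Seeds outside the mask are dropped with a warning.
#' Deterministic: ties in the flooding order are broken by insertion order.
#'
#' @param mask logical matrix (from [classify_nucleus_pixels()]).
#' @param seeds data.frame with `y`, `x` (from [detect_seeds()]).
#' @param dapi numeric matrix used as the relief.
#' @param smooth_sigma Gaussian sigma (px) applied to `dapi` before negation;
#'   0 disables smoothing.
#' @return integer label matrix; 0 = background, labels 1..k follow the
#'   retained seed order.
#' @export
watershed_segment <- function(mask, seeds, dapi, smooth_sigma = 1) {
  stopifnot(is.matrix(mask), all(dim(mask) == dim(dapi)))
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(mask) || nrow(seeds) == 0) {
    return(matrix(0L, nrow(mask), ncol(mask)))
  }
  inside <- mask[cbind(seeds$y, seeds$x)]
  if (!all(inside)) {
    warning(sum(!inside), " seed(s) outside the mask were dropped")
    seeds <- seeds[inside, , drop = FALSE]
    if (nrow(seeds) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  }
  relief <- if (smooth_sigma > 0) {
    -as.matrix(EBImage::gblur(dapi, sigma = smooth_sigma))
  } else -dapi
  seeded_watershed_cpp(relief, mask,
                       cbind(as.integer(seeds$y), as.integer(seeds$x)))
}

#' Measure segmented nuclei
#'
#' Per label: centroid, area, per-channel median intensity and the radial
#' distance of the centroid from the colony center in µm.
#'
#' @param labels integer label matrix.
#' @param colony a [colony_image()] whose channels share the label shape.
#' @param center colony center `(y, x)` in crop pixels; default the stored
#'   image center.
#' @return data.frame with `colony_id`, `label`, `y`, `x`, `area_px`,
#'   `radial_distance_um` and one median-intensity column per channel.
#' @export
measure_nuclei <- function(labels, colony, center = colony$center) {
  stopifnot(all(dim(labels) == dim(colony$channels[[1]])))
  idx <- which(labels > 0)
  chans <- names(colony$channels)
  if (length(idx) == 0) {
    out <- data.frame(colony_id = character(0), label = integer(0),
                      y = numeric(0), x = numeric(0), area_px = integer(0),
                      radial_distance_um = numeric(0))
    for (ch in chans) out[[ch]] <- numeric(0)
    return(out)
  }
  lab <- labels[idx]
  ulab <- sort(unique(lab))
  lab_f <- factor(lab, levels = ulab)
  area <- tabulate(lab_f, length(ulab))
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  cy <- rowsum(as.numeric(rows), lab_f)[, 1] / area
  cx <- rowsum(as.numeric(cols), lab_f)[, 1] / area
  out <- data.frame(colony_id = colony$colony_id, label = ulab,
                    y = cy, x = cx, area_px = area,
                    radial_distance_um = sqrt((cy - center[["y"]])^2 +
                                              (cx - center[["x"]])^2) *
                      colony$pixel_size_um,
                    row.names = NULL)
  for (ch in chans) {
    v <- colony$channels[[ch]][idx]
    out[[ch]] <- vapply(split(v, lab_f), median, numeric(1), USE.NAMES = FALSE)
  }
  out
}

#' Full nuclear segmentation of one colony
#'
#' Convenience pipeline: classify DAPI pixels, detect disk-filter seeds,
#' seeded watershed, measure nuclei.
#'
#' @param colony a [colony_image()].
#' @param seed_radius_px matched-filter radius (default: expected nucleus
#'   radius in px).
#' @param seed_threshold passed to [detect_seeds()].
#' @param min_area minimum object area; default 25% of the seed-filter disk
#'   area.
#' @param classify_method,classifier passed to [classify_nucleus_pixels()].
#' @param classify_smooth_sigma pre-smoothing for the pixel classification
#'   (default 1 px).
#' @param smooth_sigma passed to [watershed_segment()].
#' @param dapi name of the DAPI channel.
#' @return list with `mask`, `seeds`, `labels`, `records`.
#' @export
segment_colony <- function(colony, seed_radius_px = 3,
                           seed_threshold = NULL,
                           min_area = ceiling(0.25 * pi * seed_radius_px^2),
                           classify_method = "otsu", classifier = NULL,
                           classify_smooth_sigma = 1,
                           smooth_sigma = 1, dapi = "DAPI") {
  ch <- get_channel(colony, dapi)
  mask <- classify_nucleus_pixels(ch, method = classify_method,
                                  classifier = classifier, min_area = min_area,
                                  pre_smooth_sigma = classify_smooth_sigma)
  seeds <- detect_seeds(ch, filter_radius_px = seed_radius_px,
                        threshold = seed_threshold)
  labels <- watershed_segment(mask, seeds, ch, smooth_sigma = smooth_sigma)
  records <- measure_nuclei(labels, colony)
  list(mask = mask, seeds = seeds, labels = labels, records = records)
}

#' Greedy one-to-one matching of detected points to ground truth
#'
#' Repeatedly pairs the globally closest (truth, found) points within
#' `max_dist`; used for segmentation-recovery benchmarks.
#'
#' @param truth_xy,found_xy two-column matrices/data.frames of (y, x).
#' @param max_dist maximum pairing distance (px).
#' @return data.frame with `truth_idx`, `found_idx`, `dist`.
#' @export
match_points <- function(truth_xy, found_xy, max_dist = 3) {
  truth_xy <- as.matrix(truth_xy); found_xy <- as.matrix(found_xy)
  out <- data.frame(truth_idx = integer(0), found_idx = integer(0),
                    dist = numeric(0))
  if (nrow(truth_xy) == 0 || nrow(found_xy) == 0) return(out)
  d <- outer(truth_xy[, 1], found_xy[, 1], `-`)^2 +
    outer(truth_xy[, 2], found_xy[, 2], `-`)^2
  d <- sqrt(d)
  repeat {
    m <- which.min(d)
    if (length(m) == 0 || d[m] > max_dist) break
    ti <- (m - 1L) %% nrow(d) + 1L
    fi <- (m - 1L) %/% nrow(d) + 1L
    out <- rbind(out, data.frame(truth_idx = ti, found_idx = fi, dist = d[m]))
    d[ti, ] <- Inf
    d[, fi] <- Inf
    if (all(!is.finite(d))) break
  }
  out[order(out$truth_idx), , drop = FALSE]
}
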