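#' A cropped, projected multi-channel colony image
#'
#' @param channels named list of 2-D numeric matrices sharing one shape.
#' @param center numeric `(y, x)` colony center in 1-based fractional pixel
#'   coordinates of the crop.
#' @param radius_px colony radius in pixels (> 0).
#' @param pixel_size_um µm per pixel.
#' @param colony_id identifier string.
#' @return object of class `colony_image`.
#' @export
colony_image <- function(channels, center, radius_px, pixel_size_um,
                         colony_id = "colony") {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), !anyDuplicated(names(channels)),
            radius_px > 0, pixel_size_um > 0, length(center) == 2)
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) stop_config("all channels must share one shape")
  d <- dims[[1]]
  center <- setNames(as.numeric(center), c("y", "x"))
  if (center["y"] - radius_px < 0.5 || center["y"] + radius_px > d[1] + 0.5 ||
      center["x"] - radius_px < 0.5 || center["x"] + radius_px > d[2] + 0.5) {
    stop_config("colony disk does not lie fully inside the crop")
  }
  structure(list(channels = channels, center = center, radius_px = radius_px,
                 pixel_size_um = pixel_size_um, colony_id = colony_id),
            class = "colony_image")
}

#' @export
print.colony_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("colony_image", x$colony_id, ":", d[1], "x", d[2], "px, radius",
      round(x$radius_px, 1), "px,", x$pixel_size_um, "um/px, channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

get_channel <- function(colony, channel) {
  if (!channel %in% names(colony$channels)) {
    stop_config("channel '", channel, "' not present (have: ",
                paste(names(colony$channels), collapse = ", "), ")")
  }
  colony$channels[[channel]]
}

#' Detect circular colonies in a micropattern field
#'
#' Thresholds the reference channel (Otsu), fills holes, labels connected
#' components and keeps those whose equivalent diameter is within `tolerance`
#' of the expected colony diameter. Detections are returned in row-major grid
#' order (rows grouped within one colony radius in y, then left to right).
#'
#' @param channels named list of field matrices (e.g. from
#'   [max_intensity_projection()] or [make_colony_array()]).
#' @param expected_diameter_um nominal colony diameter (the micropattern
#'   island size; 500 µm for these colonies).
#' @param pixel_size_um µm per pixel.
#' @param reference channel used for detection (default `"DAPI"`).
#' @param tolerance relative tolerance on the equivalent diameter (default
#'   0.2, i.e. ±20%).
#' @return data.frame with `colony_id`, `center_y`, `center_x`, `radius_px`,
#'   `diameter_um`; zero rows when nothing is detected.
#' @export
detect_colonies <- function(channels, expected_diameter_um,
                            pixel_size_um, reference = "DAPI",
                            tolerance = 0.2) {
  stopifnot(expected_diameter_um > 0, pixel_size_um > 0)
  if (!reference %in% names(channels)) {
    stop_config("reference channel '", reference, "' not in field")
  }
  ref <- channels[[reference]]
  thr <- otsu_threshold(ref)
  mask <- EBImage::fillHull(ref > thr)
  labels <- EBImage::bwlabel(mask)
  n <- max(labels)
  empty <- data.frame(colony_id = character(0), center_y = numeric(0),
                      center_x = numeric(0), radius_px = numeric(0),
                      diameter_um = numeric(0))
  if (n == 0) {
    message("detect_colonies: no objects above threshold")
    return(empty)
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  area <- tabulate(lab, n)
  rows <- (idx - 1L) %% nrow(ref) + 1L
  cols <- (idx - 1L) %/% nrow(ref) + 1L
  cy <- rowsum(as.numeric(rows), lab)[, 1] / area
  cx <- rowsum(as.numeric(cols), lab)[, 1] / area
  diam_um <- 2 * sqrt(area / pi) * pixel_size_um
  keep <- abs(diam_um - expected_diameter_um) <= tolerance * expected_diameter_um
  if (!any(keep)) {
    message("detect_colonies: no objects within diameter tolerance")
    return(empty)
  }
  cy <- cy[keep]; cx <- cx[keep]; diam_um <- diam_um[keep]
  # row-major order: group centers into rows within one radius in y
  o <- order(cy)
  row_id <- cumsum(c(1, diff(cy[o]) > expected_diameter_um / pixel_size_um / 2))
  ord <- o[order(row_id, cx[o])]
  data.frame(colony_id = sprintf("colony_%d", seq_along(ord)),
             center_y = cy[ord], center_x = cx[ord],
             radius_px = diam_um[ord] / 2 / pixel_size_um,
             diameter_um = diam_um[ord], row.names = NULL)
}

#' Crop one detected colony out of a field
#'
#' Square crop centered on the detection, side `2 * ceiling(radius_px *
#' (1 + pad_fraction))` (+1 center pixel); pixels are copied bit-identically
#' and the center is re-expressed in crop coordinates.
#'
#' @param channels named list of field matrices.
#' @param detection one row of [detect_colonies()] output, or a list with
#'   `center_y`, `center_x`, `radius_px` (and optionally `colony_id`).
#' @param pad_fraction extra margin relative to the radius (default 0.1).
#' @param pixel_size_um µm per pixel.
#' @return a [colony_image()].
#' @export
crop_colony <- function(channels, detection, pad_fraction = 0.1,
                        pixel_size_um = 1) {
  cy <- detection$center_y; cx <- detection$center_x
  radius <- detection$radius_px
  stopifnot(length(cy) == 1, radius > 0, pad_fraction >= 0)
  half <- ceiling(radius * (1 + pad_fraction))
  d <- dim(channels[[1]])
  y0 <- round(cy) - half; y1 <- round(cy) + half
  x0 <- round(cx) - half; x1 <- round(cx) + half
  if (y0 < 1 || x0 < 1 || y1 > d[1] || x1 > d[2]) {
    stop_config("detection (with padding) lies outside the field")
  }
  crops <- lapply(channels, function(m) m[y0:y1, x0:x1, drop = FALSE])
  colony_image(crops,
               center = c(y = cy - y0 + 1, x = cx - x0 + 1),
               radius_px = radius, pixel_size_um = pixel_size_um,
               colony_id = detection$colony_id %||% "colony")
}
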