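#' Estimate the colony center
#'
#' Default: centroid of the hole-filled Otsu mask of the reference channel
#' (robust to crop placement); `"stored"` returns the center recorded on the
#' image.
#'
#' @param colony a [colony_image()].
#' @param method `"mask"` (default) or `"stored"`.
#' @param reference channel for the mask method.
#' @return numeric `(y, x)` in crop pixels.
#' @export
colony_center <- function(colony, method = c("mask", "stored"),
                          reference = "DAPI") {
  method <- match.arg(method)
  if (method == "stored") return(colony$center)
  ref <- get_channel(colony, reference)
  thr <- otsu_threshold(ref)
  mask <- EBImage::fillHull(ref > thr) > 0
  if (!any(mask)) return(colony$center)
  idx <- which(mask)
  c(y = mean((idx - 1L) %% nrow(ref) + 1L),
    x = mean((idx - 1L) %/% nrow(ref) + 1L))
}

#' Radial intensity profile of one colony channel
#'
#' Mean intensity per radial bin, measured from the colony center outward, in
#' arbitrary fluorescence units. `source = "pixels"` averages pixel
#' intensities; `source = "nuclei"` averages per-nucleus median intensities
#' (from [measure_nuclei()] records) by centroid radius — the "nuclear
#' signals" flavour of profile.
#'
#' @param colony a [colony_image()].
#' @param channel channel name.
#' @param bin_width_um radial bin width (default 5 µm).
#' @param source `"pixels"` or `"nuclei"`.
#' @param records nucleus records, required for `source = "nuclei"`.
#' @param center colony center `(y, x)`; default [colony_center()] on the
#'   image.
#' @param max_radius_um outermost radius covered (default: colony radius; a
#'   trailing partial bin is appended when the bin width does not divide it).
#' @return data.frame of class `radial_profile` with `bin_lo_um`, `bin_hi_um`,
#'   `bin_mid_um`, `mean` (NA where `n == 0`), `n`; attributes `channel`,
#'   `colony_id`, `radius_um`, `bin_width_um`, `source`, `center`.
#' @export
radial_profile <- function(colony, channel, bin_width_um = 5,
                           source = c("pixels", "nuclei"), records = NULL,
                           center = NULL, max_radius_um = NULL) {
  source <- match.arg(source)
  stopifnot(bin_width_um > 0)
  px <- colony$pixel_size_um
  radius_um <- colony$radius_px * px
  if (is.null(max_radius_um)) max_radius_um <- radius_um
  if (is.null(center)) center <- colony_center(colony)
  edges <- seq(0, max_radius_um, by = bin_width_um)
  if (edges[length(edges)] < max_radius_um) edges <- c(edges, max_radius_um)

  if (source == "pixels") {
    ch <- get_channel(colony, channel)
    r <- pixel_radius(nrow(ch), ncol(ch), center[["y"]], center[["x"]]) * px
    vals <- as.numeric(ch)
  } else {
    if (is.null(records)) stop_config("source = 'nuclei' requires records")
    if (!channel %in% names(records)) {
      stop_config("channel '", channel, "' not in records")
    }
    r <- records$radial_distance_um
    vals <- records[[channel]]
  }
  bin <- findInterval(as.numeric(r), edges, left.open = FALSE,
                      rightmost.closed = FALSE)
  keep <- bin >= 1 & bin <= length(edges) - 1L
  bin <- bin[keep]; vals <- vals[keep]
  nb <- length(edges) - 1L
  n <- tabulate(bin, nb)
  s <- rep(0, nb)
  if (length(bin)) {
    agg <- rowsum(vals, bin)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  out <- data.frame(bin_lo_um = edges[-length(edges)], bin_hi_um = edges[-1],
                    bin_mid_um = (edges[-length(edges)] + edges[-1]) / 2,
                    mean = ifelse(n > 0, s / pmax(n, 1), NA_real_), n = n)
  structure(out, class = c("radial_profile", "data.frame"),
            channel = channel, colony_id = colony$colony_id,
            radius_um = radius_um, bin_width_um = bin_width_um,
            source = source, center = center)
}

# Build a radial_profile directly from bin edges and values (internal; also
# handy in tests for analytic profiles).
profile_from_values <- function(edges_um, means, n = NULL, radius_um = NULL,
                                channel = "channel", colony_id = "colony") {
  nb <- length(edges_um) - 1L
  stopifnot(length(means) == nb)
  if (is.null(n)) n <- rep(1L, nb)
  structure(
    data.frame(bin_lo_um = edges_um[-length(edges_um)], bin_hi_um = edges_um[-1],
               bin_mid_um = (edges_um[-length(edges_um)] + edges_um[-1]) / 2,
               mean = means, n = n),
    class = c("radial_profile", "data.frame"), channel = channel,
    colony_id = colony_id, radius_um = radius_um %||% max(edges_um),
    bin_width_um = edges_um[2] - edges_um[1], source = "values",
    center = c(y = NA_real_, x = NA_real_))
}

#' Aggregate radial profiles across colonies
#'
#' Rescales each profile to fractional radius (r / colony radius), interpolates
#' onto a common fractional grid and reports the per-bin mean, SD and SEM
#' across colonies. Optionally normalizes each colony's profile by its own
#' pixel-weighted mean first.
#'
#' @param profiles list of [radial_profile()]s.
#' @param normalization `"none"` or `"colony-mean"` (divide each profile by
#'   its pixel-count-weighted mean).
#' @param n_bins number of fractional-radius bins (default: bin count of the
#'   first profile).
#' @return data.frame with `frac_mid`, `mean`, `sd`, `sem`, `n_colonies`.
#' @export
aggregate_profiles <- function(profiles, normalization = c("none", "colony-mean"),
                               n_bins = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(length(profiles) >= 1)
  n_bins <- n_bins %||% nrow(profiles[[1]])
  grid <- (seq_len(n_bins) - 0.5) / n_bins
  mat <- vapply(profiles, function(p) {
    R <- attr(p, "radius_um")
    if (is.null(R) || !is.finite(R)) stop_config("profile lacks a colony radius")
    y <- p$mean
    if (normalization == "colony-mean") {
      w <- sum(y * p$n, na.rm = TRUE) / sum(p$n[!is.na(y)])
      if (!is.finite(w) || w == 0) stop_config("cannot normalize a zero-mean profile")
      y <- y / w
    }
    ok <- !is.na(y)
    if (sum(ok) < 2) stop_config("profile has fewer than 2 usable bins")
    approx(p$bin_mid_um[ok] / R, y[ok], xout = grid, rule = 2)$y
  }, numeric(n_bins))
  mat <- matrix(mat, nrow = n_bins)
  data.frame(frac_mid = grid,
             mean = rowMeans(mat),
             sd = apply(mat, 1, sd),
             sem = apply(mat, 1, sd) / sqrt(ncol(mat)),
             n_colonies = ncol(mat))
}

#' Average intensity at the colony edge
#'
#' Pixel-count-weighted mean over the bins whose centers lie in the outermost
#' `edge_fraction` of the colony radius.
#'
#' @param profile a [radial_profile()].
#' @param edge_fraction fraction of the radius counted as "edge" (default 0.1).
#' @return scalar intensity; NA (with a warning) when no bin falls in the
#'   window.
#' @export
edge_average <- function(profile, edge_fraction = 0.1) {
  stopifnot(edge_fraction > 0, edge_fraction < 1)
  R <- attr(profile, "radius_um")
  sel <- profile$bin_mid_um >= (1 - edge_fraction) * R &
    profile$bin_mid_um <= R & profile$n > 0 & !is.na(profile$mean)
  if (!any(sel)) {
    warning("no populated bins in the edge window")
    return(NA_real_)
  }
  sum(profile$mean[sel] * profile$n[sel]) / sum(profile$n[sel])
}

#' Radius of the half-maximal intensity of a peripheral domain
#'
#' On the smoothed profile, the smallest radius at which intensity first
#' reaches halfway between baseline and maximum, by linear interpolation
#' between bin centers. The baseline is the minimum over bins interior to the
#' maximum, so this reads the rising (inner) flank of a peripheral domain —
#' the boundary between the central territory and a marker ring. Undefined
#' (NA with a `reason` attribute) when the profile is flat or contrast is
#' below `contrast_floor` times the profile maximum.
#'
#' @param profile a [radial_profile()].
#' @param smoothing_bins moving-average window in bins (default 3).
#' @param contrast_floor minimum (max − baseline) as a fraction of the
#'   profile maximum (default 0.1).
#' @return radius in µm, or NA with attribute `reason`.
#' @export
half_max_radius <- function(profile, smoothing_bins = 3, contrast_floor = 0.1) {
  ok <- !is.na(profile$mean) & profile$n > 0
  if (sum(ok) < 3) {
    return(structure(NA_real_, reason = "fewer than 3 usable bins"))
  }
  x <- profile$bin_mid_um[ok]
  y <- profile$mean[ok]
  s <- moving_average(y, smoothing_bins)
  i_max <- which.max(s)
  if (i_max == 1) {
    return(structure(NA_real_, reason = "no domain: maximum at the innermost bin"))
  }
  baseline <- min(s[seq_len(i_max)])
  amp <- s[i_max] - baseline
  if (!is.finite(amp) || amp < contrast_floor * max(abs(s))) {
    return(structure(NA_real_, reason = "contrast below floor (no domain)"))
  }
  half <- baseline + amp / 2
  for (k in seq_len(i_max)) {
    if (s[k] >= half) {
      if (k == 1) return(x[1])
      return(x[k - 1] + (half - s[k - 1]) / (s[k] - s[k - 1]) *
               (x[k] - x[k - 1]))
    }
  }
  structure(NA_real_, reason = "no crossing found")  # unreachable
}

# Centered moving average; ends use the available shorter window.
moving_average <- function(y, w) {
  if (w <= 1) return(y)
  half <- floor(w / 2)
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}
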