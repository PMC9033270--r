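# Threshold spec parser: "otsu", "fixed:<v>", or a bare number.
resolve_threshold <- function(x, values) {
  if (is.numeric(x)) return(x)
  if (identical(x, "otsu")) return(otsu_threshold(values))
  if (is.character(x) && startsWith(x, "fixed:")) {
    return(as.numeric(sub("^fixed:", "", x)))
  }
  stop_config("threshold must be 'otsu', 'fixed:<v>' or a number")
}

#' Marker-positive area fraction, normalized to the reference channel
#'
#' Fraction of the reference-positive (colony-occupied) area that is also
#' marker-positive: `|marker+ & reference+| / |reference+|`. The reference
#' mask is hole-filled so it represents the occupied colony area.
#'
#' @param colony a [colony_image()].
#' @param marker marker channel name.
#' @param reference reference channel (default `"DAPI"`).
#' @param threshold_method `"otsu"`, `"fixed:<v>"` or a number, applied to the
#'   marker; the reference always uses Otsu.
#' @return fraction in `[0, 1]`; NA (with warning) when the reference area is
#'   empty.
#' @export
positive_area_fraction <- function(colony, marker, reference = "DAPI",
                                   threshold_method = "otsu") {
  ref <- get_channel(colony, reference)
  mk <- get_channel(colony, marker)
  ref_mask <- EBImage::fillHull(ref > otsu_threshold(ref)) > 0
  if (!any(ref_mask)) {
    warning("empty reference area; fraction undefined")
    return(NA_real_)
  }
  mk_mask <- mk > resolve_threshold(threshold_method, mk)
  sum(mk_mask & ref_mask) / sum(ref_mask)
}

#' Area fraction of the central marker-positive domain
#'
#' Area of the largest marker-positive connected component containing (or
#' nearest to) the colony center, divided by the colony disk area. Differs
#' from [positive_area_fraction()] by restricting to the central component,
#' so detached peripheral specks are excluded.
#'
#' @param colony a [colony_image()].
#' @param marker marker channel.
#' @param threshold_method as in [positive_area_fraction()].
#' @param center colony center; default [colony_center()].
#' @return fraction in `[0, 1]`; 0 when no positive component exists.
#' @export
central_domain_fraction <- function(colony, marker, threshold_method = "otsu",
                                    center = NULL) {
  mk <- get_channel(colony, marker)
  if (is.null(center)) center <- colony_center(colony)
  mask <- EBImage::fillHull(mk > resolve_threshold(threshold_method, mk)) > 0
  if (!any(mask)) return(0)
  lab <- EBImage::bwlabel(mask)
  cy <- round(center[["y"]]); cx <- round(center[["x"]])
  sel <- 0L
  if (cy >= 1 && cy <= nrow(lab) && cx >= 1 && cx <= ncol(lab)) {
    sel <- lab[cy, cx]
  }
  if (sel == 0L) {
    # nearest component centroid to the center
    idx <- which(lab > 0)
    l <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    a <- tabulate(l, max(lab))
    ccy <- rowsum(as.numeric(rows), l)[, 1] / a[a > 0]
    ccx <- rowsum(as.numeric(cols), l)[, 1] / a[a > 0]
    comp <- sort(unique(l))
    sel <- comp[which.min((ccy - center[["y"]])^2 + (ccx - center[["x"]])^2)]
  }
  sum(lab == sel) / (pi * colony$radius_px^2)
}

#' Normalize per-nucleus marker signals
#'
#' `"per-colony-median-dapi"` (default) divides each nucleus's marker median
#' by that colony's median nuclear DAPI, making values comparable across
#' colonies and exposures; `"per-colony-zscore"` standardizes within colony.
#'
#' @param records nucleus records ([measure_nuclei()] output, possibly several
#'   colonies row-bound).
#' @param channel marker channel column.
#' @param method normalization method.
#' @param dapi DAPI column name.
#' @return `records` with an added `normalized` column and a
#'   `normalization` attribute; colonies with a zero divisor get NA with a
#'   warning.
#' @export
normalize_nuclear_signal <- function(records, channel,
                                     method = c("per-colony-median-dapi",
                                                "per-colony-zscore"),
                                     dapi = "DAPI") {
  method <- match.arg(method)
  stopifnot(channel %in% names(records))
  out <- records
  out$normalized <- NA_real_
  for (cid in unique(records$colony_id)) {
    i <- records$colony_id == cid
    v <- records[[channel]][i]
    if (method == "per-colony-median-dapi") {
      if (!dapi %in% names(records)) stop_config("no '", dapi, "' column")
      d <- median(records[[dapi]][i])
      if (!is.finite(d) || d == 0) {
        warning("zero median DAPI in colony ", cid, "; values undefined")
      } else out$normalized[i] <- v / d
    } else {
      s <- sd(v)
      out$normalized[i] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
    }
  }
  attr(out, "normalization") <- method
  out
}

#' Mitotic index from pH3-positive nuclei
#'
#' Fraction of nuclei whose pH3 median intensity exceeds the threshold.
#'
#' @param records nucleus records.
#' @param ph3_channel pH3 column name.
#' @param threshold a number, `"fixed:<v>"`, or `"otsu-on-medians"` (Otsu over
#'   the per-nucleus medians).
#' @return fraction in `[0, 1]`; NA (with warning) for zero nuclei.
#' @export
mitotic_index <- function(records, ph3_channel = "pH3",
                          threshold = "otsu-on-medians") {
  if (nrow(records) == 0) {
    warning("no nuclei; mitotic index undefined")
    return(NA_real_)
  }
  stopifnot(ph3_channel %in% names(records))
  v <- records[[ph3_channel]]
  thr <- if (identical(threshold, "otsu-on-medians")) {
    otsu_threshold(v)
  } else resolve_threshold(threshold, v)
  mean(v > thr)
}
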