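#' Ground truth for one synthetic micropatterned colony
#'
#' Describes a circular micropatterned colony (default 500 µm diameter, the
#' standard island size for neuruloid culture) with Gaussian-blob nuclei, an
#' optional central marker disk (a "PAX6-like" domain), an optional peripheral
#' Gaussian annulus (a "SOX10-like" domain), optional mitotic nuclei carrying a
#' pH3-like channel, per-channel backgrounds and a noise model. Nucleus centers
#' are sampled uniformly in the colony under a minimum center-to-center
#' separation (dart throwing), so watershed separability can be controlled.
#'
#' All randomness (nucleus placement, per-nucleus levels, mitotic assignment)
#' is consumed here under `seed`; [make_colony_image()] renders the truth and
#' only draws pixel noise, so a fixed truth plus a fixed render seed gives
#' byte-identical images.
#'
#' @param colony_radius_um colony radius in µm (default 250 = 500 µm diameter).
#' @param pixel_size_um physical pixel size, µm per pixel.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_sigma_um Gaussian blob sigma in µm; blobs are truncated at
#'   3 sigma, which also defines the nucleus footprint.
#' @param min_separation_um minimum center-to-center distance (default
#'   `3 * nucleus_sigma_um`, guaranteeing watershed separability).
#' @param nucleus_shape `"gaussian"` (default) or `"disk"` (flat plateau over
#'   the footprint; useful for idealized threshold tests).
#' @param nuclear_channels named numeric vector of mean peak levels for
#'   nucleus-borne channels; must include `"DAPI"`. Non-DAPI nuclear channels
#'   are rendered as flat plateaus over each nucleus footprint so that the
#'   per-nucleus median of a noise-free image equals the planted level.
#' @param nuclear_level_cv lognormal coefficient of variation of per-nucleus
#'   levels around the channel mean.
#' @param central_channel,central_disk_radius_um,central_level name, radius and
#'   plateau level of the central marker disk; `central_channel = NULL` omits it.
#' @param ring_channel,ring_center_radius_um,ring_sigma_um,ring_level name,
#'   center radius, width and peak level of the peripheral Gaussian annulus;
#'   `ring_channel = NULL` omits it.
#' @param mitotic_fraction fraction of nuclei flagged mitotic (planted count =
#'   `round(fraction * n_nuclei)`); when positive a `"pH3"` channel is added
#'   with `ph3_levels["positive"]` on mitotic nuclei and
#'   `ph3_levels["negative"]` on the rest.
#' @param ph3_levels named vector `c(positive = , negative = )`.
#' @param confluent_dapi_level optional uniform DAPI plateau over the whole
#'   colony disk (emulates a confluent epithelium where DAPI tiles the colony);
#'   0 disables it.
#' @param background scalar or named per-channel background intensity.
#' @param noise `list(type = "poisson")`, `list(type = "gaussian", sd = )` or
#'   `list(type = "none")`.
#' @param margin_um blank margin around the colony in the rendered canvas.
#' @param seed integer RNG seed.
#'
#' @return An object of class `colony_truth`: all parameters plus `nuclei`, a
#'   data.frame with 1-based fractional pixel coordinates `y`, `x`, `sigma_px`,
#'   `mitotic`, and one level column per nuclear channel; `center` (y, x) and
#'   `canvas_px` of the render target; and `channel_names`.
#' @seealso [make_colony_image()], [make_colony_array()], [truth_masks()]
#' @export
colony_truth <- function(colony_radius_um = 250,
                         pixel_size_um = 2,
                         n_nuclei = 120,
                         nucleus_sigma_um = 6,
                         min_separation_um = 3 * nucleus_sigma_um,
                         nucleus_shape = c("gaussian", "disk"),
                         nuclear_channels = c(DAPI = 100),
                         nuclear_level_cv = 0.1,
                         central_channel = "PAX6",
                         central_disk_radius_um = 125,
                         central_level = 100,
                         ring_channel = "SOX10",
                         ring_center_radius_um = 175,
                         ring_sigma_um = 15,
                         ring_level = 100,
                         mitotic_fraction = 0,
                         ph3_levels = c(positive = 100, negative = 10),
                         confluent_dapi_level = 0,
                         background = 10,
                         noise = list(type = "poisson"),
                         margin_um = 20,
                         seed = 1) {
  nucleus_shape <- match.arg(nucleus_shape)
  stopifnot(colony_radius_um > 0, pixel_size_um > 0, n_nuclei >= 0,
            nucleus_sigma_um > 0, min_separation_um >= 0)
  if (!"DAPI" %in% names(nuclear_channels)) {
    stop_config("nuclear_channels must include a 'DAPI' entry")
  }
  if (!is.null(central_channel) && central_disk_radius_um > colony_radius_um) {
    stop_config("central_disk_radius_um must not exceed colony_radius_um")
  }
  if (!is.null(ring_channel) && ring_center_radius_um > colony_radius_um) {
    stop_config("ring_center_radius_um must not exceed colony_radius_um")
  }
  noise$type <- match.arg(noise$type, c("poisson", "gaussian", "none"))
  if (noise$type == "gaussian" && is.null(noise$sd)) {
    stop_config("gaussian noise requires a 'sd' entry")
  }

  if (mitotic_fraction > 0 && !"pH3" %in% names(nuclear_channels)) {
    nuclear_channels <- c(nuclear_channels, pH3 = unname(ph3_levels["positive"]))
  }

  radius_px <- colony_radius_um / pixel_size_um
  canvas_px <- 2L * ceiling(radius_px + margin_um / pixel_size_um) + 1L
  center <- c(y = (canvas_px + 1) / 2, x = (canvas_px + 1) / 2)
  sigma_px <- nucleus_sigma_um / pixel_size_um

  nuclei <- with_seed(seed, {
    pts <- sample_colony_points(
      n_nuclei,
      max_radius_px = radius_px - 3 * sigma_px,
      min_sep_px = min_separation_um / pixel_size_um
    )
    df <- data.frame(y = center[["y"]] + pts$dy, x = center[["x"]] + pts$dx,
                     sigma_px = rep(sigma_px, nrow(pts)), row.names = NULL)
    n_mit <- round(mitotic_fraction * n_nuclei)
    df$mitotic <- logical(nrow(df))
    if (n_mit > 0) df$mitotic[sample.int(n_nuclei, n_mit)] <- TRUE
    for (ch in names(nuclear_channels)) {
      lv <- nuclear_channels[[ch]]
      base <- if (nuclear_level_cv > 0) {
        sdlog <- sqrt(log(1 + nuclear_level_cv^2))
        lv * rlnorm(n_nuclei, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(lv, n_nuclei)
      if (ch == "pH3" && mitotic_fraction > 0) {
        base <- ifelse(df$mitotic,
                       base,
                       base / lv * ph3_levels[["negative"]])
      }
      df[[ch]] <- base
    }
    df
  })

  channel_names <- unique(c(names(nuclear_channels), central_channel, ring_channel))
  bg <- expand_per_channel(background, channel_names, "background")

  structure(list(
    colony_radius_um = colony_radius_um, pixel_size_um = pixel_size_um,
    radius_px = radius_px, canvas_px = canvas_px, center = center,
    nucleus_sigma_um = nucleus_sigma_um, min_separation_um = min_separation_um,
    nucleus_shape = nucleus_shape, nuclear_channels = nuclear_channels,
    central_channel = central_channel,
    central_disk_radius_um = if (is.null(central_channel)) NA_real_ else central_disk_radius_um,
    central_level = central_level,
    ring_channel = ring_channel,
    ring_center_radius_um = if (is.null(ring_channel)) NA_real_ else ring_center_radius_um,
    ring_sigma_um = ring_sigma_um, ring_level = ring_level,
    mitotic_fraction = mitotic_fraction, ph3_levels = ph3_levels,
    confluent_dapi_level = confluent_dapi_level,
    background = bg, noise = noise, nuclei = nuclei,
    channel_names = channel_names, seed = seed
  ), class = "colony_truth")
}

# Dart-throwing placement of n points uniform in a disk of max_radius_px with
# pairwise separation >= min_sep_px. Offsets (dy, dx) relative to the center.
sample_colony_points <- function(n, max_radius_px, min_sep_px,
                                 max_tries = 20000L) {
  if (n == 0) return(data.frame(dy = numeric(0), dx = numeric(0)))
  if (max_radius_px <= 0) stop_config("colony too small for the nucleus size")
  ys <- xs <- numeric(n)
  placed <- 0L
  for (i in seq_len(max_tries)) {
    r <- max_radius_px * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    dy <- r * sin(th); dx <- r * cos(th)
    if (placed == 0L ||
        min((ys[seq_len(placed)] - dy)^2 + (xs[seq_len(placed)] - dx)^2) >=
          min_sep_px^2) {
      placed <- placed + 1L
      ys[placed] <- dy; xs[placed] <- dx
      if (placed == n) break
    }
  }
  if (placed < n) {
    stop_config("could not place ", n, " nuclei at separation ", min_sep_px,
                " px; reduce n_nuclei or min_separation_um")
  }
  data.frame(dy = ys, dx = xs)
}

expand_per_channel <- function(x, channel_names, what) {
  if (is.null(names(x))) {
    if (length(x) != 1) stop_config(what, " must be scalar or fully named")
    return(setNames(rep(as.numeric(x), length(channel_names)), channel_names))
  }
  out <- setNames(rep(0, length(channel_names)), channel_names)
  bad <- setdiff(names(x), channel_names)
  if (length(bad)) stop_config(what, " names not among channels: ",
                               paste(bad, collapse = ", "))
  out[names(x)] <- as.numeric(x)
  out
}

#' @export
print.colony_truth <- function(x, ...) {
  cat("colony_truth:", nrow(x$nuclei), "nuclei, radius", x$colony_radius_um,
      "um,", x$pixel_size_um, "um/px, channels:",
      paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

# Noise-free signal channels (no background), as a named list of matrices.
render_colony_signal <- function(truth, canvas_px = truth$canvas_px,
                                 center = truth$center) {
  nr <- nc <- canvas_px
  if (center["y"] + truth$radius_px > nr + 0.5 ||
      center["y"] - truth$radius_px < 0.5 ||
      center["x"] + truth$radius_px > nc + 0.5 ||
      center["x"] - truth$radius_px < 0.5) {
    stop_config("colony does not fit in the canvas")
  }
  r_px <- pixel_radius(nr, nc, center["y"], center["x"])
  r_um <- r_px * truth$pixel_size_um
  colony_disk <- r_um <= truth$colony_radius_um
  chans <- lapply(truth$channel_names, function(ch) matrix(0, nr, nc))
  names(chans) <- truth$channel_names

  # nucleus-borne channels
  nuc <- truth$nuclei
  nuclear_names <- names(truth$nuclear_channels)
  for (i in seq_len(nrow(nuc))) {
    s <- nuc$sigma_px[i]
    rad <- 3 * s
    y0 <- max(1L, floor(nuc$y[i] - rad)); y1 <- min(nr, ceiling(nuc$y[i] + rad))
    x0 <- max(1L, floor(nuc$x[i] - rad)); x1 <- min(nc, ceiling(nuc$x[i] + rad))
    dy <- (y0:y1) - nuc$y[i]; dx <- (x0:x1) - nuc$x[i]
    d2 <- outer(dy^2, dx^2, `+`)
    inside <- d2 <= rad^2
    for (ch in nuclear_names) {
      lv <- nuc[[ch]][i]
      patch <- chans[[ch]][y0:y1, x0:x1]
      if (ch == "DAPI" && truth$nucleus_shape == "gaussian") {
        patch <- patch + lv * exp(-d2 / (2 * s^2)) * inside
      } else {
        # flat plateau over the footprint; overlaps take the max so the
        # planted level remains the true per-nucleus value
        patch <- pmax(patch, lv * inside)
      }
      chans[[ch]][y0:y1, x0:x1] <- patch
    }
  }
  if (truth$confluent_dapi_level > 0) {
    chans$DAPI <- pmax(chans$DAPI, truth$confluent_dapi_level * colony_disk)
  }
  if (!is.null(truth$central_channel)) {
    chans[[truth$central_channel]] <- chans[[truth$central_channel]] +
      truth$central_level * (r_um <= truth$central_disk_radius_um)
  }
  if (!is.null(truth$ring_channel)) {
    chans[[truth$ring_channel]] <- chans[[truth$ring_channel]] +
      truth$ring_level *
        exp(-(r_um - truth$ring_center_radius_um)^2 / (2 * truth$ring_sigma_um^2))
  }
  chans
}

apply_noise <- function(channels, noise, seed) {
  if (noise$type == "none") return(channels)
  with_seed(seed, {
    for (ch in names(channels)) {
      m <- channels[[ch]]
      channels[[ch]] <- switch(noise$type,
        poisson = matrix(rpois(length(m), lambda = pmax(m, 0)),
                         nrow(m), ncol(m)),
        gaussian = m + matrix(rnorm(length(m), sd = noise$sd),
                              nrow(m), ncol(m))
      )
    }
    channels
  })
}

#' Render a synthetic colony image from its ground truth
#'
#' Renders every channel of a [colony_truth()]: DAPI as Gaussian blobs (or flat
#' disks), non-DAPI nuclear channels as flat plateaus at the planted
#' per-nucleus level, the central marker as a disk, the peripheral marker as a
#' Gaussian annulus; adds per-channel background and applies the truth's noise
#' model. Deterministic for a fixed truth and `seed`.
#'
#' @param truth a [colony_truth()].
#' @param seed seed for the pixel noise (default: the truth's own seed).
#' @param colony_id identifier stored on the resulting image.
#' @return list with `image` (a [colony_image()]) and the unchanged `truth`.
#' @export
make_colony_image <- function(truth, seed = truth$seed, colony_id = "colony_1") {
  stopifnot(inherits(truth, "colony_truth"))
  chans <- render_colony_signal(truth)
  for (ch in names(chans)) chans[[ch]] <- chans[[ch]] + truth$background[[ch]]
  chans <- apply_noise(chans, truth$noise, seed)
  img <- colony_image(chans, center = truth$center, radius_px = truth$radius_px,
                      pixel_size_um = truth$pixel_size_um, colony_id = colony_id)
  list(image = img, truth = truth)
}

#' Render a micropattern array of synthetic colonies
#'
#' Places `n_colonies` copies of a truth template on a row-major grid with
#' optional center jitter, re-drawing nuclei per colony (seeds derived from
#' `seed`), and renders one multi-channel field with shared background and
#' noise. Emulates a micropattern array for colony-detection tests.
#'
#' @param n_colonies number of colonies (>= 1).
#' @param truth_template a [colony_truth()] used as parameter template.
#' @param jitter_um uniform center jitter half-range, µm.
#' @param spacing_um grid pitch; must exceed colony diameter + 2 * jitter.
#' @param seed RNG seed controlling per-colony truths, jitter and noise.
#' @return list with `channels` (named list of field matrices) and `truths`
#'   (list of per-colony [colony_truth()] objects, grid order, with `center`
#'   in field coordinates).
#' @export
make_colony_array <- function(n_colonies, truth_template, jitter_um = 0,
                              spacing_um = 2 * truth_template$colony_radius_um +
                                60 + 2 * jitter_um,
                              seed = truth_template$seed) {
  stopifnot(inherits(truth_template, "colony_truth"), n_colonies >= 1)
  if (spacing_um <= 2 * truth_template$colony_radius_um + 2 * jitter_um) {
    stop_config("spacing_um too small: colonies would overlap")
  }
  px <- truth_template$pixel_size_um
  ncols <- ceiling(sqrt(n_colonies))
  nrows <- ceiling(n_colonies / ncols)
  pitch_px <- spacing_um / px
  field_nr <- ceiling(nrows * pitch_px)
  field_nc <- ceiling(ncols * pitch_px)
  field <- lapply(truth_template$channel_names,
                  function(ch) matrix(0, field_nr, field_nc))
  names(field) <- truth_template$channel_names

  truths <- vector("list", n_colonies)
  with_seed(seed, {
    k <- 0L
    for (i in seq_len(nrows)) {
      for (j in seq_len(ncols)) {
        if (k >= n_colonies) break
        k <- k + 1L
        sub_seed <- sample.int(.Machine$integer.max, 1L)
        tr <- truth_template
        tr$seed <- sub_seed
        tr <- do.call(colony_truth, truth_params(tr))
        cy <- (i - 0.5) * pitch_px + runif(1, -jitter_um, jitter_um) / px
        cx <- (j - 0.5) * pitch_px + runif(1, -jitter_um, jitter_um) / px
        sig <- render_colony_signal(tr, canvas_px = tr$canvas_px)
        # paste the colony canvas additively into the field
        half <- (tr$canvas_px - 1) / 2
        y0 <- round(cy) - half; x0 <- round(cx) - half
        if (y0 < 1 || x0 < 1 || y0 + tr$canvas_px - 1 > field_nr ||
            x0 + tr$canvas_px - 1 > field_nc) {
          stop_config("colony ", k, " does not fit in the field")
        }
        ys <- y0:(y0 + tr$canvas_px - 1); xs <- x0:(x0 + tr$canvas_px - 1)
        for (ch in names(field)) {
          field[[ch]][ys, xs] <- field[[ch]][ys, xs] + sig[[ch]]
        }
        tr$center <- c(y = unname(tr$center["y"] + y0 - 1),
                       x = unname(tr$center["x"] + x0 - 1))
        tr$nuclei$y <- tr$nuclei$y + y0 - 1
        tr$nuclei$x <- tr$nuclei$x + x0 - 1
        tr$field_origin <- c(y = y0, x = x0)
        truths[[k]] <- tr
      }
    }
    for (ch in names(field)) {
      field[[ch]] <- field[[ch]] + truth_template$background[[ch]]
    }
    noise_seed <- sample.int(.Machine$integer.max, 1L)
    field <- apply_noise(field, truth_template$noise, noise_seed)
  })
  list(channels = field, truths = truths)
}

# Re-extract the constructor arguments of a colony_truth (used to re-draw
# nuclei under a new seed).
truth_params <- function(truth) {
  list(colony_radius_um = truth$colony_radius_um,
       pixel_size_um = truth$pixel_size_um,
       n_nuclei = nrow(truth$nuclei),
       nucleus_sigma_um = truth$nucleus_sigma_um,
       min_separation_um = truth$min_separation_um,
       nucleus_shape = truth$nucleus_shape,
       nuclear_channels = truth$nuclear_channels,
       central_channel = truth$central_channel,
       central_disk_radius_um = if (is.na(truth$central_disk_radius_um)) 125 else truth$central_disk_radius_um,
       central_level = truth$central_level,
       ring_channel = truth$ring_channel,
       ring_center_radius_um = if (is.na(truth$ring_center_radius_um)) 175 else truth$ring_center_radius_um,
       ring_sigma_um = truth$ring_sigma_um,
       ring_level = truth$ring_level,
       mitotic_fraction = truth$mitotic_fraction,
       ph3_levels = truth$ph3_levels,
       confluent_dapi_level = truth$confluent_dapi_level,
       background = truth$background,
       noise = truth$noise,
       seed = truth$seed)
}

#' Analytic ground-truth masks for a synthetic colony
#'
#' @param truth a [colony_truth()].
#' @return list of logical matrices on the truth's canvas: `colony` (colony
#'   disk), `nuclei` (union of 3-sigma nucleus footprints), `central` (central
#'   marker disk; all-`FALSE` when absent), plus `nucleus_labels`, an integer
#'   matrix assigning each nucleus-footprint pixel to its nearest nucleus.
#' @export
truth_masks <- function(truth) {
  nr <- nc <- truth$canvas_px
  r_um <- pixel_radius(nr, nc, truth$center["y"], truth$center["x"]) *
    truth$pixel_size_um
  colony <- r_um <= truth$colony_radius_um
  central <- if (!is.null(truth$central_channel)) {
    r_um <= truth$central_disk_radius_um
  } else matrix(FALSE, nr, nc)
  labels <- matrix(0L, nr, nc)
  best <- matrix(Inf, nr, nc)
  nucmask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(truth$nuclei))) {
    s <- truth$nuclei$sigma_px[i]; rad <- 3 * s
    y0 <- max(1L, floor(truth$nuclei$y[i] - rad))
    y1 <- min(nr, ceiling(truth$nuclei$y[i] + rad))
    x0 <- max(1L, floor(truth$nuclei$x[i] - rad))
    x1 <- min(nc, ceiling(truth$nuclei$x[i] + rad))
    dy <- (y0:y1) - truth$nuclei$y[i]; dx <- (x0:x1) - truth$nuclei$x[i]
    d2 <- outer(dy^2, dx^2, `+`)
    inside <- d2 <= rad^2
    nucmask[y0:y1, x0:x1] <- nucmask[y0:y1, x0:x1] | inside
    sub_best <- best[y0:y1, x0:x1]
    take <- inside & d2 < sub_best
    sub_lab <- labels[y0:y1, x0:x1]
    sub_lab[take] <- i
    sub_best[take] <- d2[take]
    labels[y0:y1, x0:x1] <- sub_lab
    best[y0:y1, x0:x1] <- sub_best
  }
  list(colony = colony, nuclei = nucmask, central = central,
       nucleus_labels = labels)
}
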