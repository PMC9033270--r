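#' Multi-channel z-stack container
#'
#' @param channels named list; each element a numeric matrix (single z-slice)
#'   or a 3-D array indexed `[y, x, z]`. All channels must share dimensions.
#' @param pixel_size_um physical pixel size in µm/pixel.
#' @return object of class `mc_stack` with fields `channels` (3-D arrays),
#'   `channel_names`, `z_count`, `pixel_size_um`.
#' @export
mc_stack <- function(channels, pixel_size_um = 1) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), !anyDuplicated(names(channels)),
            pixel_size_um > 0)
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    stopifnot(length(dim(ch)) == 3)
    ch
  })
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) stop_config("all channels must share dimensions")
  structure(list(channels = channels, channel_names = names(channels),
                 z_count = dims[[1]][3], pixel_size_um = pixel_size_um),
            class = "mc_stack")
}

#' @export
print.mc_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("mc_stack:", d[1], "x", d[2], "px,", x$z_count, "z,",
      length(x$channels), "channels (", paste(x$channel_names, collapse = ", "),
      "),", x$pixel_size_um, "um/px\n")
  invisible(x)
}

# TIFF pages are written z-major, channel-minor: (z1,c1), (z1,c2), ...
# Intensities are stored as 16-bit integers (camera-count convention), so
# integer-valued data in [0, 65535] round-trips exactly.
STACK_SCALE <- 65535

#' Write a multi-channel stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered z-major, channel-minor and stored 16-bit. Channel names,
#' z order and pixel size go in a `<path>.json` sidecar (the installed TIFF
#' writer does not persist per-page description tags).
#'
#' @param stack an [mc_stack()] (or a named list of matrices, treated as one
#'   z-slice).
#' @param path output TIFF path.
#' @param pixel_size_um used when `stack` is a bare list of matrices.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, pixel_size_um = 1) {
  if (!inherits(stack, "mc_stack")) stack <- mc_stack(stack, pixel_size_um)
  pages <- list()
  for (z in seq_len(stack$z_count)) {
    for (ch in stack$channel_names) {
      m <- stack$channels[[ch]][, , z]
      if (min(m) < 0 || max(m) > STACK_SCALE) {
        stop_config("intensities must lie in [0, ", STACK_SCALE,
                    "] for 16-bit storage")
      }
      pages[[length(pages) + 1L]] <- m / STACK_SCALE
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(channels = stack$channel_names, z_count = stack$z_count,
               pixel_size_um = stack$pixel_size_um, page_order = "z-major",
               scale = STACK_SCALE)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), paste0(path, ".json"))
  invisible(path)
}

#' Load a multi-channel TIFF stack
#'
#' Reads a multi-page TIFF. Channel names, z count and pixel size are taken
#' from the `<path>.json` sidecar written by [write_stack()] when present;
#' otherwise `channel_map` (channel names in page order within each z-group,
#' pages assumed z-major) is required, and a missing pixel size defaults to
#' 1 µm/px with a warning. 16-bit (8-bit) pages are rescaled to integer camera
#' counts 0..65535 (0..255), so integer data written by [write_stack()] is
#' recovered bit-exactly.
#'
#' @param path TIFF file.
#' @param channel_map character vector of channel names (page order within a
#'   z-group); overrides the sidecar when given.
#' @param pixel_size_um overrides/supplies the pixel size.
#' @return an [mc_stack()].
#' @export
load_stack <- function(path, channel_map = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop_config("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (is.matrix(pages) || !is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::fromJSON(paste(readLines(meta_path, warn = FALSE), collapse = ""))
  } else NULL
  channels <- channel_map %||% meta$channels
  if (is.null(channels)) {
    stop_config("no metadata sidecar found; supply channel_map")
  }
  if (length(pages) %% length(channels) != 0) {
    stop_config("page count ", length(pages),
                " is not a multiple of the number of channels")
  }
  px <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(px)) {
    warning("pixel size not found; defaulting to 1 um/px")
    px <- 1
  }
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  scale <- if (bits <= 8) 255 else STACK_SCALE
  nz <- length(pages) %/% length(channels)
  d <- dim(pages[[1]])[1:2]
  out <- lapply(seq_along(channels), function(ci) {
    arr <- array(0, dim = c(d[1], d[2], nz))
    for (z in seq_len(nz)) {
      pg <- pages[[(z - 1L) * length(channels) + ci]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]  # grayscale written as 1-sample
      arr[, , z] <- round(pg * scale)
    }
    arr
  })
  names(out) <- channels
  mc_stack(out, pixel_size_um = px)
}

#' Maximum-intensity projection of a stack
#'
#' Per channel, each output pixel is the maximum over z of that pixel
#' (projection of at least four z-slices is the convention for these colony
#' images; any `z_count >= 1` is accepted and recorded).
#'
#' @param stack an [mc_stack()].
#' @return named list of 2-D matrices (one per channel), with attributes
#'   `pixel_size_um` and `z_count`.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "mc_stack"), stack$z_count >= 1)
  out <- lapply(stack$channels, function(arr) {
    d <- dim(arr)
    m <- matrix(arr[, , 1], d[1], d[2])
    if (d[3] > 1) for (z in 2:d[3]) m <- pmax(m, matrix(arr[, , z], d[1], d[2]))
    m
  })
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  attr(out, "z_count") <- stack$z_count
  out
}
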