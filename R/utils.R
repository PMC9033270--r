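# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Otsu threshold in the data's own units; Inf for (near-)constant images so
# that `x > otsu_threshold(x)` yields an empty mask.
otsu_threshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!all(is.finite(rng)) || diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    return(Inf)
  }
  scaled <- matrix((x - rng[1]) / diff(rng), ncol = 1)
  thr01 <- EBImage::otsu(scaled, range = c(0, 1), levels = 256L)
  rng[1] + thr01 * diff(rng)
}

# Normalized disk kernel of radius r (px): mean filter over the disk support.
disk_kernel <- function(radius_px) {
  stopifnot(radius_px > 0)
  r <- ceiling(radius_px)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  inside <- with(g, dy^2 + dx^2 <= radius_px^2)
  k <- matrix(as.numeric(inside), nrow = 2L * r + 1L)
  k / sum(k)
}

# Squared distance of every pixel of an nr x nc image from (cy, cx) (1-based
# fractional row/col), in pixels.
pixel_radius <- function(nr, nc, cy, cx) {
  dy <- (seq_len(nr) - cy)
  dx <- (seq_len(nc) - cx)
  sqrt(outer(dy^2, dx^2, `+`))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)
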