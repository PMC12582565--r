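# Internal helpers shared across modules.
#
# Image convention: a 2D image is a numeric matrix indexed [x, y]; the first
# dimension is x, the second y. Angles are measured in degrees from the +x
# axis towards +y and, for orientations (which have no head or tail), are
# reported modulo 180.

# Evaluate `code` under set.seed(seed) and restore the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Reduce an orientation (undirected angle) to [0, 180).
deg_mod180 <- function(d) {
  d <- d %% 180
  neg <- which(d < 0)
  d[neg] <- d[neg] + 180
  d
}

# Acute difference between two orientations, in [0, 90].
acute_angle_diff <- function(a, b) {
  d <- abs(deg_mod180(a) - deg_mod180(b))
  pmin(d, 180 - d)
}

# Exact 90-degree counter-clockwise rotation of an [x, y] matrix.
rot90_mat <- function(m) {
  r <- t(m)
  r[, rev(seq_len(ncol(r))), drop = FALSE]
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Accept an image_stack or a bare numeric matrix/array; return the pixels.
as_pixels <- function(x) {
  if (inherits(x, "image_stack")) x$pixels else x
}

# Calibration attached to an image, or a supplied/default fallback.
get_calibration <- function(x, calibration = NULL) {
  if (!is.null(calibration)) return(calibration)
  if (inherits(x, "image_stack")) return(x$calibration)
  if (inherits(x, "cell_mask")) return(x$calibration)
  stop("no pixel calibration available; supply `calibration`", call. = FALSE)
}

as_mask_matrix <- function(mask) {
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  if (is.logical(m)) m else m > 0
}

# x/y coordinates (um) of pixel centers for an nx-by-ny grid, origin at the
# corner of the frame: pixel i spans [(i-1)*px, i*px], center (i-0.5)*px.
pixel_centers_um <- function(n, pixel_size_um) {
  (seq_len(n) - 0.5) * pixel_size_um
}

gaussian_kernel_1d <- function(sigma_px, derivative = FALSE) {
  r <- max(1L, ceiling(3 * sigma_px))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  if (derivative) -x / sigma_px^2 * g else g
}

# Separable 2D convolution with circular boundary (FFT via EBImage::filter2).
convolve_sep <- function(img, kx, ky) {
  k <- outer(kx, ky)
  as.matrix(EBImage::filter2(img, k))
}

gaussian_smooth <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  k <- gaussian_kernel_1d(sigma_px)
  convolve_sep(img, k, k)
}
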