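#' Richardson-Lucy deconvolution with a Gaussian PSF
#'
#' Iterative maximum-likelihood deblurring used to sharpen MT images before
#' orientation analysis. The point-spread function is an isotropic Gaussian
#' parameterized in micrometers. Richardson-Lucy updates are multiplicative,
#' so the result stays non-negative and (with the flux-preserving circular
#' convolution used here) conserves total intensity to well under 1%.
#'
#' @param image An [image_stack()] (2D) or numeric matrix.
#' @param psf_sigma_um PSF sigma in micrometers (> 0).
#' @param iterations Number of RL iterations (>= 1). More iterations
#'   sharpen further but amplify noise; 30 is a conventional default.
#' @param calibration Required when `image` is a bare matrix.
#' @return Deconvolved image, same class and shape as the input.
#' @export
#' @examples
#' cal <- pixel_calibration(0.1)
#' img <- matrix(0, 64, 64); img[32, 32] <- 100
#' blurred <- image_stack(as.matrix(EBImage::gblur(img, 2)), cal)
#' sharp <- richardson_lucy_deconvolve(blurred, 0.2, iterations = 20)
#' max(sharp$pixels) > max(blurred$pixels)
richardson_lucy_deconvolve <- function(image, psf_sigma_um, iterations = 30,
                                       calibration = NULL) {
  stopifnot_scalar_pos(psf_sigma_um, "psf_sigma_um")
  if (!is.numeric(iterations) || length(iterations) != 1L ||
      iterations < 1 || iterations != round(iterations)) {
    stop("`iterations` must be a positive integer", call. = FALSE)
  }
  calibration <- get_calibration(image, calibration)
  d <- as_pixels(image)
  if (length(dim(d)) != 2L) stop("image must be 2D", call. = FALSE)
  if (any(!is.finite(d))) stop("image has non-finite pixels", call. = FALSE)

  sigma_px <- psf_sigma_um / calibration$pixel_size_um
  k <- gaussian_kernel_1d(sigma_px)
  conv <- function(x) convolve_sep(x, k, k)  # symmetric kernel = its flip
  eps <- 1e-12
  u <- pmax(d, eps)
  for (it in seq_len(iterations)) {
    est <- conv(u)
    u <- u * conv(d / pmax(est, eps))
    u <- pmax(u, 0)
  }
  if (inherits(image, "image_stack")) {
    image_stack(u, calibration, channel = image$channel)
  } else {
    u
  }
}

#' Maximum-intensity projection over a ventral z-range
#'
#' Projects a z-stack onto 2D by taking the per-pixel maximum over the
#' optical slices whose depth falls in `z_range_um`. Slice depths are
#' measured from the first (ventral) slice at 0 in steps of the
#' calibration's `z_step_um`; the range is half-open, `[lo, hi)`, so a
#' 1.2 um ventral range over a 0.4 um-step stack selects exactly the
#' slices at 0, 0.4 and 0.8 um.
#'
#' @param stack An [image_stack()] with `dim3 = "z"`.
#' @param z_range_um Either a single value `h` (range `[0, h)`) or
#'   `c(lo, hi)`; `NULL` projects the whole stack.
#' @return A 2D [image_stack()].
#' @export
max_intensity_projection <- function(stack, z_range_um = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$dim3 != "z") stop("stack has no z dimension", call. = FALSE)
  z <- stack_z(stack)
  if (is.null(z_range_um)) {
    sel <- seq_along(z)
  } else {
    if (length(z_range_um) == 1L) z_range_um <- c(0, z_range_um)
    sel <- which(z >= z_range_um[1] & z < z_range_um[2])
  }
  if (!length(sel)) stop("z range selects no slices", call. = FALSE)
  out <- stack$pixels[, , sel[1]]
  for (k in sel[-1]) out <- pmax(out, stack$pixels[, , k])
  cal <- stack$calibration
  image_stack(out, pixel_calibration(cal$pixel_size_um,
                                     frame_interval_s = cal$frame_interval_s),
              channel = stack$channel)
}

#' IsoData (intermeans) automatic threshold within a mask
#'
#' Classic iterative intermeans thresholding: starting from the midpoint of
#' the intensity range of the in-mask pixels, the threshold is repeatedly
#' replaced by the mean of the average intensity below and above it until
#' it converges. Binarization is restricted to the mask.
#'
#' @param image An [image_stack()] or matrix.
#' @param mask A `cell_mask` or binary matrix; only in-mask pixels inform
#'   the threshold, and the output is zero outside it.
#' @return A `threshold_result`: list with `mask` (logical MT mask, a
#'   subset of the cell mask), `method`, and `threshold`.
#' @export
isodata_threshold <- function(image, mask) {
  d <- as_pixels(image)
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  v <- d[m]
  thr <- isodata_value(v)
  structure(list(mask = (d >= thr) & m, method = "isodata_global",
                 threshold = thr),
            class = "threshold_result")
}

# IsoData iteration on a vector of intensities.
isodata_value <- function(v, tol = NULL) {
  rng <- range(v)
  if (diff(rng) == 0) {
    stop("cannot threshold a constant image region", call. = FALSE)
  }
  if (is.null(tol)) tol <- 1e-8 * diff(rng)
  thr <- mean(rng)
  for (it in 1:200) {
    lo <- v[v < thr]; hi <- v[v >= thr]
    if (!length(lo) || !length(hi)) break
    new <- (mean(lo) + mean(hi)) / 2
    if (abs(new - thr) <= tol) { thr <- new; break }
    thr <- new
  }
  thr
}

#' Per-cell "perfect" threshold optimized for the peripheral MT array
#'
#' Chooses the threshold from the peripheral band only — IsoData restricted
#' to the outer `band_width_um` of the cell — so that it is optimized for
#' the sub-membrane MT array of that particular cell, then binarizes the
#' whole cell with it. A manual `override` value replaces the automatic
#' choice, for parity with interactive use.
#'
#' @param image An [image_stack()] or matrix.
#' @param mask A `cell_mask` or binary matrix.
#' @param band_width_um Width of the peripheral band (default 1 um, the
#'   directionality band).
#' @param calibration Required when neither image nor mask carries one.
#' @param override Optional manual threshold value.
#' @return A `threshold_result` with `method = "per_cell_perfect"`.
#' @export
per_cell_perfect_threshold <- function(image, mask, band_width_um = 1,
                                       calibration = NULL, override = NULL) {
  stopifnot_scalar_pos(band_width_um, "band_width_um")
  calibration <- tryCatch(get_calibration(image, calibration),
                          error = function(e) get_calibration(mask))
  d <- as_pixels(image)
  m <- as_mask_matrix(mask)
  band <- peripheral_band(mask, band_width_um, calibration)
  if (!any(band)) stop("peripheral band is empty", call. = FALSE)
  thr <- if (!is.null(override)) override else isodata_value(d[band])
  structure(list(mask = (d >= thr) & m, method = "per_cell_perfect",
                 threshold = thr),
            class = "threshold_result")
}

#' Fixed-value threshold within a mask
#' @param image An [image_stack()] or matrix.
#' @param mask Binary mask.
#' @param value Threshold value.
#' @return A `threshold_result` with `method = "fixed"`.
#' @export
fixed_threshold <- function(image, mask, value) {
  d <- as_pixels(image)
  m <- as_mask_matrix(mask)
  structure(list(mask = (d >= value) & m, method = "fixed",
                 threshold = value),
            class = "threshold_result")
}

#' Population-standard threshold across a batch of cells
#'
#' The "standard threshold across the analyzed cell population": IsoData on
#' the pooled in-mask intensities of all cells in a batch, applied
#' uniformly to each cell.
#'
#' @param images List of images (one per cell).
#' @param masks List of matching masks.
#' @return List of `threshold_result`, one per cell, sharing one threshold
#'   value (`method = "population_standard"`).
#' @export
population_standard_threshold <- function(images, masks) {
  stopifnot(length(images) == length(masks), length(images) >= 1L)
  pooled <- unlist(lapply(seq_along(images), function(k) {
    as_pixels(images[[k]])[as_mask_matrix(masks[[k]])]
  }))
  thr <- isodata_value(pooled)
  lapply(seq_along(images), function(k) {
    d <- as_pixels(images[[k]]); m <- as_mask_matrix(masks[[k]])
    structure(list(mask = (d >= thr) & m, method = "population_standard",
                   threshold = thr),
              class = "threshold_result")
  })
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold_result [%s]: T = %.4g, %d MT pixels\n",
              x$method, x$threshold, sum(x$mask)))
  invisible(x)
}

#' Peripheral band of a cell mask
#'
#' The set of in-mask pixels within `width_um` of the cell border —
#' "the outer `width_um`" of the cell. Bands are monotone in width:
#' `peripheral_band(m, w1)` is a subset of `peripheral_band(m, w2)` for
#' `w1 <= w2`.
#'
#' @param mask A `cell_mask` or binary matrix.
#' @param width_um Band width in micrometers (> 0).
#' @param calibration Required when `mask` is a bare matrix.
#' @return Logical matrix of the band (same shape as the mask).
#' @export
peripheral_band <- function(mask, width_um, calibration = NULL) {
  stopifnot_scalar_pos(width_um, "width_um")
  calibration <- get_calibration(mask, calibration)
  geom <- compute_border_geometry(mask, calibration)
  band <- !is.na(geom$distance_um) & geom$distance_um <= width_um
  band
}
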