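#' Per-pixel MT orientation by the structure tensor
#'
#' Estimates the local filament orientation at every pixel from the image
#' structure tensor: Gaussian-derivative gradients (sigma
#' `gradient_sigma_um`) are accumulated into the tensor with a Gaussian
#' window (sigma `window_sigma_um`), and the orientation of the tensor's
#' minor eigenvector — the along-ridge direction — is reported in degrees
#' modulo 180. Coherence, `(l1 - l2) / (l1 + l2)` of the tensor
#' eigenvalues, measures how anisotropic (trustworthy) the estimate is.
#'
#' A pixel is *valid* (conclusive) when it is MT-positive under the
#' supplied threshold mask and its coherence reaches `coherence_min`;
#' every other pixel is disregarded downstream, which is how inconclusive
#' pixels are handled throughout the analysis.
#'
#' @param image An [image_stack()] or matrix (2D).
#' @param mt_mask MT-positive pixels: a `threshold_result` or logical
#'   matrix.
#' @param gradient_sigma_um Derivative-of-Gaussian sigma (default one
#'   pixel at the default 0.1 um calibration).
#' @param window_sigma_um Tensor-window sigma (default two pixels).
#' @param coherence_min Validity cut-off in `[0, 1]`.
#' @param cell_mask Optional cell footprint. When given, the image is
#'   extended beyond the cell border (each outside pixel takes the value
#'   of nearby inside pixels) before gradients are computed, so that the
#'   intensity step at the cell edge does not masquerade as a
#'   border-parallel structure in peripheral pixels.
#' @param calibration Required when `image` is a bare matrix.
#' @return An `orientation_field`: list with matrices `orientation_deg`
#'   (`NA` where invalid), `coherence`, `valid`, and the parameters used.
#'   If no pixel is valid the field is returned empty with a warning
#'   recorded in `$warning`.
#' @export
compute_orientation_field <- function(image, mt_mask,
                                      gradient_sigma_um = 0.1,
                                      window_sigma_um = 0.2,
                                      coherence_min = 0.2,
                                      cell_mask = NULL,
                                      calibration = NULL) {
  stopifnot_scalar_pos(gradient_sigma_um, "gradient_sigma_um")
  stopifnot_scalar_pos(window_sigma_um, "window_sigma_um")
  calibration <- get_calibration(image, calibration)
  d <- as_pixels(image)
  if (length(dim(d)) != 2L) stop("image must be 2D", call. = FALSE)
  m <- if (inherits(mt_mask, "threshold_result")) mt_mask$mask else
    as_mask_matrix(mt_mask)
  px <- calibration$pixel_size_um
  if (!is.null(cell_mask)) {
    d <- extend_border(d, as_mask_matrix(cell_mask))
  }

  sg <- gradient_sigma_um / px
  sw <- window_sigma_um / px
  g <- gaussian_kernel_1d(sg)
  dg <- gaussian_kernel_1d(sg, derivative = TRUE)
  gx <- convolve_sep(d, dg, g)
  gy <- convolve_sep(d, g, dg)
  Jxx <- gaussian_smooth(gx * gx, sw)
  Jyy <- gaussian_smooth(gy * gy, sw)
  Jxy <- gaussian_smooth(gx * gy, sw)

  eps <- 1e-12
  # 2*theta of the major eigenvector (dominant gradient direction); the
  # ridge runs perpendicular to it.
  theta_major <- 0.5 * atan2(2 * Jxy, Jxx - Jyy)
  orientation <- deg_mod180(rad2deg(theta_major) + 90)
  coherence <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / (Jxx + Jyy + eps)
  coherence[coherence > 1] <- 1

  valid <- m & coherence >= coherence_min
  orientation[!valid] <- NA_real_
  warn <- NULL
  if (!any(valid)) {
    warn <- "no conclusive pixels: empty orientation field"
    warning(warn, call. = FALSE)
  }
  structure(list(orientation_deg = orientation, coherence = coherence,
                 valid = valid,
                 params = list(gradient_sigma_um = gradient_sigma_um,
                               window_sigma_um = window_sigma_um,
                               coherence_min = coherence_min),
                 warning = warn),
            class = "orientation_field")
}

# Replace outside-mask pixels by a smooth extension of in-mask intensities
# (iterative 3x3 averaging of already-known pixels), removing the cell-edge
# intensity step before gradient computation.
extend_border <- function(img, mask, iterations = 10L) {
  box <- matrix(1, 3, 3)
  fill <- img
  fill[!mask] <- 0
  known <- mask
  for (k in seq_len(iterations)) {
    s <- as.matrix(EBImage::filter2(fill, box))
    c <- as.matrix(EBImage::filter2(known * 1, box))
    new <- !known & c > 1e-9
    if (!any(new)) break
    fill[new] <- s[new] / c[new]
    known <- known | new
  }
  fill[!known] <- mean(img[mask])
  fill
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("orientation_field: %d x %d px, %d conclusive pixels\n",
              nrow(x$valid), ncol(x$valid), sum(x$valid)))
  invisible(x)
}

#' Angle between MT orientation and the local border tangent
#'
#' For every conclusive pixel, the acute angle between the MT orientation
#' and the border tangent at the nearest border point:
#' `alpha = min(|delta|, 180 - |delta|)` with `delta` taken modulo 180.
#' 0 degrees means the MT runs parallel to the cell edge, 90 degrees
#' perpendicular to it.
#'
#' @param field An [compute_orientation_field()] result.
#' @param geom A [compute_border_geometry()] result of the same shape.
#' @return Matrix of angles in `[0, 90]` (`NA` where invalid), class
#'   `angle_map`.
#' @export
angle_to_border <- function(field, geom) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(geom, "border_geometry"))
  if (!all(dim(field$valid) == dim(geom$mask))) {
    stop("orientation field and border geometry shapes differ",
         call. = FALSE)
  }
  a <- acute_angle_diff(field$orientation_deg, geom$tangent_deg)
  a[!field$valid | is.na(geom$tangent_deg)] <- NA_real_
  structure(a, class = c("angle_map", "matrix"))
}
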