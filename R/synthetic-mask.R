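#' Generate a synthetic single-cell mask
#'
#' Produces the binary footprint of one cell on a calibrated pixel grid.
#' Shapes are smooth by construction (ellipse, superellipse, or a
#' low-order-Fourier "smoothed polygon") so that border tangents are well
#' defined at the analysis scale; an optional `roughness` term perturbs the
#' radius for stress tests.
#'
#' @param shape `"ellipse"`, `"superellipse"`, or `"smoothed_polygon"`.
#' @param size_um Semi-axes `c(a, b)` in micrometers (a single value is
#'   recycled to a circle).
#' @param calibration A [pixel_calibration()]; sets the pixel size.
#' @param seed Integer seed; the mask is bitwise reproducible for a fixed
#'   seed and parameter set.
#' @param frame_um Side length of the square image frame in micrometers.
#'   Default: twice the larger semi-axis plus a 6 um margin. The requested
#'   cell must fit inside the frame.
#' @param exponent Superellipse exponent (> 0); 2 recovers the ellipse,
#'   larger values square off the outline.
#' @param n_harmonics Number of random Fourier harmonics for
#'   `"smoothed_polygon"`.
#' @param roughness Relative radial amplitude of the harmonics (0 = smooth).
#' @return A `cell_mask`: list with `mask` (logical `[x, y]` matrix, a
#'   single 4-connected component without holes) and `calibration`.
#' @export
#' @examples
#' m <- generate_cell_mask("ellipse", size_um = c(15, 10), seed = 1)
#' sum(m$mask) * m$calibration$pixel_size_um^2  # close to pi * 15 * 10
generate_cell_mask <- function(shape = c("ellipse", "superellipse",
                                         "smoothed_polygon"),
                               size_um = c(15, 10),
                               calibration = pixel_calibration(),
                               seed = 1,
                               frame_um = NULL,
                               exponent = 3,
                               n_harmonics = 4,
                               roughness = 0.08) {
  shape <- match.arg(shape)
  if (length(size_um) == 1L) size_um <- rep(size_um, 2)
  if (any(size_um <= 0)) stop("`size_um` must be positive", call. = FALSE)
  px <- calibration$pixel_size_um
  if (is.null(frame_um)) frame_um <- 2 * max(size_um) + 6
  if (2 * max(size_um) > frame_um) {
    stop("requested cell size exceeds the image frame", call. = FALSE)
  }
  n <- round(frame_um / px)
  cx <- frame_um / 2
  xs <- pixel_centers_um(n, px) - cx
  ys <- xs
  X <- matrix(xs, n, n)
  Y <- matrix(ys, n, n, byrow = TRUE)
  a <- size_um[1]; b <- size_um[2]

  mask <- with_seed(seed, {
    switch(shape,
      ellipse = (X / a)^2 + (Y / b)^2 <= 1,
      superellipse = abs(X / a)^exponent + abs(Y / b)^exponent <= 1,
      smoothed_polygon = {
        k <- seq_len(n_harmonics) + 1  # orders 2..n+1 keep the centroid put
        amp <- stats::runif(n_harmonics, 0, roughness)
        pha <- stats::runif(n_harmonics, 0, 2 * pi)
        th <- atan2(Y / b, X / a)
        mod <- 1 + colSums(amp * sin(outer(k, as.vector(th)) +
                                     pha))  # radius modulation
        r <- sqrt((X / a)^2 + (Y / b)^2)
        r <= matrix(mod, n, n) / (1 + sum(amp))  # keep inside frame
      })
  })
  mask <- keep_largest_component(mask)
  mask <- fill_holes(mask)
  if (!any(mask)) stop("generated mask is empty", call. = FALSE)
  structure(list(mask = mask, calibration = calibration, shape = shape,
                 size_um = size_um, frame_um = frame_um, seed = seed),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  area <- sum(x$mask) * x$calibration$pixel_size_um^2
  cat(sprintf("cell_mask (%s): %d x %d px, area %.1f um^2\n",
              x$shape %||% "supplied", nrow(x$mask), ncol(x$mask), area))
  invisible(x)
}

#' Wrap a supplied binary matrix as a cell mask
#'
#' Validates that the footprint is a single non-empty connected component.
#'
#' @param mask Logical or 0/1 matrix, `[x, y]`.
#' @param calibration A [pixel_calibration()].
#' @return A `cell_mask` with provenance `"supplied"`.
#' @export
as_cell_mask <- function(mask, calibration) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  lab <- EBImage::bwlabel(m * 1)
  if (max(lab) != 1L) {
    stop("mask must contain exactly one connected component", call. = FALSE)
  }
  structure(list(mask = m, calibration = calibration, shape = NULL,
                 provenance = "supplied"),
            class = "cell_mask")
}

keep_largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  lab == which.max(sizes)
}

# Fill background holes: any background component not touching the frame
# edge is inside the cell.
fill_holes <- function(mask) {
  bg <- EBImage::bwlabel((!mask) * 1)
  edge_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  edge_labels <- edge_labels[edge_labels > 0]
  hole <- (!mask) & !(bg %in% edge_labels)
  mask | matrix(hole, nrow(mask), ncol(mask))
}
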