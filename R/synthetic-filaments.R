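#' Specification of a synthetic filament population
#'
#' Describes how microtubule-like filaments are drawn into a cell mask:
#' how many, how they are oriented relative to the cell border, their
#' geometry, brightness, the imaging blur, and the noise model.
#'
#' Orientation models:
#' * `"parallel_to_border"` — each filament is traced along the local
#'   border-tangent field from its seed point, i.e. it follows an
#'   iso-distance contour (emulates the aligned sub-membrane MT array);
#' * `"isotropic"` — straight filaments with orientation uniform on
#'   `[0, 180)`;
#' * `"fixed_angle"` — straight filaments at `fixed_angle_deg` degrees
#'   (in `[0, 90]`) to the border tangent at their seed point.
#'
#' @param n_filaments Number of filaments (>= 0).
#' @param orientation_model One of the three models above.
#' @param fixed_angle_deg Angle to the border for `"fixed_angle"`.
#' @param length_um,thickness_um Filament length and apparent thickness.
#' @param intensity Peak filament intensity, arbitrary units.
#' @param background Constant background level added before noise.
#' @param psf_sigma_um Gaussian point-spread-function sigma.
#' @param noise_poisson_scale Photon-counting scale: counts are drawn as
#'   `Pois(intensity * scale) / scale`; 0 disables shot noise.
#' @param noise_gaussian_sd Read-noise standard deviation; 0 disables.
#' @param seed_band_um Optional `c(min, max)` distance-to-border range for
#'   filament seed points; `NULL` seeds uniformly over the whole mask.
#' @return A `filament_spec` list.
#' @export
filament_spec <- function(n_filaments = 60,
                          orientation_model = c("parallel_to_border",
                                                "isotropic", "fixed_angle"),
                          fixed_angle_deg = NULL,
                          length_um = 5,
                          thickness_um = 0.3,
                          intensity = 100,
                          background = 5,
                          psf_sigma_um = 0.15,
                          noise_poisson_scale = 1,
                          noise_gaussian_sd = 2,
                          seed_band_um = NULL) {
  orientation_model <- match.arg(orientation_model)
  if (n_filaments < 0 || n_filaments != round(n_filaments)) {
    stop("`n_filaments` must be a non-negative integer", call. = FALSE)
  }
  stopifnot_scalar_pos(length_um, "length_um")
  stopifnot_scalar_pos(thickness_um, "thickness_um")
  stopifnot_scalar_pos(intensity, "intensity")
  stopifnot_scalar_pos(psf_sigma_um, "psf_sigma_um")
  if (orientation_model == "fixed_angle") {
    if (is.null(fixed_angle_deg) || fixed_angle_deg < 0 ||
        fixed_angle_deg > 90) {
      stop("`fixed_angle_deg` must be given in [0, 90]", call. = FALSE)
    }
  }
  if (noise_poisson_scale < 0 || noise_gaussian_sd < 0 || background < 0) {
    stop("noise and background parameters must be non-negative",
         call. = FALSE)
  }
  structure(list(n_filaments = n_filaments,
                 orientation_model = orientation_model,
                 fixed_angle_deg = fixed_angle_deg,
                 length_um = length_um, thickness_um = thickness_um,
                 intensity = intensity, background = background,
                 psf_sigma_um = psf_sigma_um,
                 noise_poisson_scale = noise_poisson_scale,
                 noise_gaussian_sd = noise_gaussian_sd,
                 seed_band_um = seed_band_um),
            class = "filament_spec")
}

#' Render a synthetic MT image with analytic ground truth
#'
#' Draws a filament population (see [filament_spec()]) inside a cell mask,
#' convolves it with a Gaussian PSF, and adds Poisson and Gaussian noise.
#' Alongside the image, the generator records the ground truth the
#' downstream analyses are validated against: each filament's analytic
#' angle to the border tangent at its nearest border point, a noiseless
#' per-pixel orientation map, and the noiseless filament pixel mask.
#'
#' @param mask A `cell_mask` (non-empty).
#' @param spec A [filament_spec()].
#' @param seed Integer seed; output is bitwise reproducible.
#' @return A list with
#'   * `image`: the noisy rendered [image_stack()];
#'   * `truth`: list with `angle_to_border_deg` (one value per rendered
#'     filament, in `[0, 90]`), `orientation_map` (degrees in `[0, 180)`,
#'     `NA` off-filament), `filament_mask` (logical, coverage >= 0.5),
#'     `noiseless` (pre-noise, pre-background image), and `n_rendered`.
#' @export
#' @examples
#' m <- generate_cell_mask("ellipse", c(12, 9), seed = 1)
#' r <- render_mt_image(m, filament_spec(n_filaments = 20), seed = 2)
#' range(r$truth$angle_to_border_deg)
render_mt_image <- function(mask, spec, seed = 1) {
  stopifnot(inherits(spec, "filament_spec"))
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  calibration <- get_calibration(mask)
  px <- calibration$pixel_size_um
  geom <- compute_border_geometry(mask, calibration)
  nx <- nrow(m); ny <- ncol(m)

  canvas <- matrix(0, nx, ny)
  cover <- matrix(0, nx, ny)
  orient_map <- matrix(NA_real_, nx, ny)
  truth_angles <- numeric(0)

  with_seed(seed, {
    candidates <- which(m)
    if (!is.null(spec$seed_band_um)) {
      d <- geom$distance_um[candidates]
      keep <- d >= spec$seed_band_um[1] & d <= spec$seed_band_um[2]
      if (any(keep)) candidates <- candidates[keep]
    }
    for (f in seq_len(spec$n_filaments)) {
      idx <- candidates[sample.int(length(candidates), 1L)]
      i0 <- (idx - 1L) %% nx + 1L
      j0 <- (idx - 1L) %/% nx + 1L
      x0 <- (i0 - 0.5 + stats::runif(1, -0.5, 0.5)) * px
      y0 <- (j0 - 0.5 + stats::runif(1, -0.5, 0.5)) * px
      tr <- switch(spec$orientation_model,
        parallel_to_border = trace_along_tangent(geom, x0, y0,
                                                 spec$length_um),
        fixed_angle = {
          t0 <- tangent_direction_at(geom, x0, y0)
          sgn <- if (stats::runif(1) < 0.5) 1 else -1
          trace_straight(m, px, x0, y0,
                         t0 + sgn * deg2rad(spec$fixed_angle_deg),
                         spec$length_um)
        },
        isotropic = trace_straight(m, px, x0, y0,
                                   stats::runif(1, 0, pi),
                                   spec$length_um))
      if (is.null(tr) || nrow(tr$points) < 3L) next
      st <- stamp_polyline(nx, ny, tr$points / px + 0.5, tr$dirs,
                           spec$thickness_um / px)
      if (is.null(st)) next
      sel <- st$idx
      replace <- st$coverage > cover[sel]
      cover[sel][replace] <- st$coverage[replace]
      canvas[sel] <- pmax(canvas[sel], spec$intensity * st$coverage)
      on_fil <- replace & st$coverage >= 0.5
      orient_map[sel][on_fil] <- st$orientation_deg[on_fil]

      mid <- tr$points[ceiling(nrow(tr$points) / 2), ]
      mdir <- tr$dirs[ceiling(nrow(tr$points) / 2)]
      tang <- rad2deg(tangent_direction_at(geom, mid[1], mid[2]))
      truth_angles <- c(truth_angles, acute_angle_diff(mdir, tang))
    }

    noiseless <- canvas
    blurred <- gaussian_smooth(canvas, spec$psf_sigma_um / px) +
      spec$background
    noisy <- blurred
    if (spec$noise_poisson_scale > 0) {
      noisy <- stats::rpois(length(blurred),
                            blurred * spec$noise_poisson_scale) /
        spec$noise_poisson_scale
      noisy <- matrix(noisy, nx, ny)
    }
    if (spec$noise_gaussian_sd > 0) {
      noisy <- noisy + matrix(stats::rnorm(length(noisy), 0,
                                           spec$noise_gaussian_sd), nx, ny)
    }
    noisy[noisy < 0] <- 0

    list(
      image = image_stack(noisy, calibration, channel = "tubulin"),
      truth = list(angle_to_border_deg = truth_angles,
                   orientation_map = orient_map,
                   filament_mask = cover >= 0.5,
                   noiseless = noiseless,
                   n_rendered = length(truth_angles)),
      geometry = geom
    )
  })
}

# --- filament tracing -------------------------------------------------------

# Follow the border-tangent field from (x0, y0), half the length in each
# direction. Returns points (um) and the local direction (deg mod 180) at
# each point, or NULL if the seed is unusable.
trace_along_tangent <- function(geom, x0, y0, length_um, step_um = NULL) {
  px <- geom$calibration$pixel_size_um
  if (is.null(step_um)) step_um <- 0.25 * px
  n_half <- ceiling(length_um / 2 / step_um)
  t0 <- tangent_direction_at(geom, x0, y0)
  v0 <- c(cos(t0), sin(t0))
  walk <- function(sign) {
    pts <- matrix(NA_real_, n_half, 2)
    p <- c(x0, y0); v <- sign * v0
    for (k in seq_len(n_half)) {
      th <- tangent_direction_at(geom, p[1], p[2])
      cand <- c(cos(th), sin(th))
      if (sum(cand * v) < 0) cand <- -cand
      v <- cand
      p <- p + step_um * v
      if (!point_in_mask(geom$mask, px, p)) break
      pts[k, ] <- p
    }
    pts[!is.na(pts[, 1]), , drop = FALSE]
  }
  fwd <- walk(1); bwd <- walk(-1)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(c(x0, y0), 1), fwd)
  if (nrow(pts) < 3L) return(NULL)
  dirs <- segment_orientations(pts)
  list(points = pts, dirs = dirs)
}

# Straight filament centered at (x0, y0) along orientation theta (radians),
# clipped to the mask.
trace_straight <- function(mask, px, x0, y0, theta, length_um,
                           step_um = NULL) {
  if (is.null(step_um)) step_um <- 0.25 * px
  v <- c(cos(theta), sin(theta))
  s <- seq(-length_um / 2, length_um / 2, by = step_um)
  pts <- cbind(x0 + s * v[1], y0 + s * v[2])
  inside <- vapply(seq_len(nrow(pts)),
                   function(k) point_in_mask(mask, px, pts[k, ]),
                   logical(1))
  # keep the contiguous run containing the seed
  mid <- which.min(abs(s))
  if (!inside[mid]) return(NULL)
  lo <- mid; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- mid; while (hi < length(s) && inside[hi + 1]) hi <- hi + 1
  pts <- pts[lo:hi, , drop = FALSE]
  if (nrow(pts) < 3L) return(NULL)
  list(points = pts, dirs = rep(deg_mod180(rad2deg(theta)), nrow(pts)))
}

point_in_mask <- function(mask, px, p) {
  i <- round(p[1] / px + 0.5); j <- round(p[2] / px + 0.5)
  i >= 1 && i <= nrow(mask) && j >= 1 && j <= ncol(mask) && mask[i, j]
}

# Orientation (deg mod 180) of the local step at each polyline point.
segment_orientations <- function(pts) {
  n <- nrow(pts)
  nxt <- pts[c(2:n, n), , drop = FALSE]
  prv <- pts[c(1, 1:(n - 1)), , drop = FALSE]
  deg_mod180(rad2deg(atan2(nxt[, 2] - prv[, 2], nxt[, 1] - prv[, 1])))
}

# Anti-aliased stamp of a polyline of given thickness (all units pixels).
# Returns linear pixel indices, coverage in [0, 1], and the orientation of
# the nearest polyline point for each covered pixel.
stamp_polyline <- function(nx, ny, pts_px, dirs_deg, thickness_px) {
  half <- thickness_px / 2
  pad <- ceiling(half + 1.5)
  i_rng <- floor(min(pts_px[, 1]) - pad):ceiling(max(pts_px[, 1]) + pad)
  j_rng <- floor(min(pts_px[, 2]) - pad):ceiling(max(pts_px[, 2]) + pad)
  i_rng <- i_rng[i_rng >= 1 & i_rng <= nx]
  j_rng <- j_rng[j_rng >= 1 & j_rng <= ny]
  if (!length(i_rng) || !length(j_rng)) return(NULL)
  gi <- rep(i_rng, times = length(j_rng))
  gj <- rep(j_rng, each = length(i_rng))
  # squared distance from every bbox pixel to every polyline point
  d2 <- outer(gi, pts_px[, 1], "-")^2 + outer(gj, pts_px[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_along(gi), nearest)])
  coverage <- pmin(pmax(half + 0.5 - dmin, 0), 1)
  keep <- coverage > 0
  if (!any(keep)) return(NULL)
  list(idx = (gj[keep] - 1L) * nx + gi[keep],
       coverage = coverage[keep],
       orientation_deg = dirs_deg[nearest[keep]])
}
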