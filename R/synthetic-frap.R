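#' Simulate a belt-FRAP time-lapse with known sliding ground truth
#'
#' Builds a post-bleach time series of a cell in which fluorescent signal
#' at frame 0 exists only inside a central unbleached belt, and a known
#' number of filaments then translocate out of the belt into the bleached
#' zones at constant speed — the situation the displaced-area readout of
#' [displaced_mt_area()] is meant to quantify. The ground truth records,
#' for every frame, the noiseless rendered filament area inside the
#' bleached zones.
#'
#' Static belt filaments run along the belt stripe; translocating
#' filaments run along the sliding axis, start fully inside the belt,
#' slide lengthwise (alternating to either side), and stop when they
#' reach the cell edge. Bleached zones may
#' retain a configurable residual of the pre-bleach signal to emulate
#' incomplete bleaching (default 0: fully bleached).
#'
#' @param mask A `cell_mask`.
#' @param belt_geometry List with `belt_width_um` (default 5) and `axis`
#'   (`"x"` or `"y"`, default `"x"`).
#' @param sliding List with `n_translocating` (>= 0), `speed_um_s`
#'   (default 0.02), and optionally `n_static` belt filaments (default 12).
#' @param n_frames Number of frames (>= 2).
#' @param calibration A [pixel_calibration()] with `frame_interval_s`;
#'   default: FRAP preset (10 s interval) at the mask's pixel size.
#' @param seed Integer seed.
#' @param filament_length_um,thickness_um,intensity,background,psf_sigma_um
#'   Render settings; FRAP filaments default to 0.5 um thickness (sliding
#'   MT bundles appear thicker than single stained MTs).
#' @param noise_poisson_scale,noise_gaussian_sd Noise model as in
#'   [filament_spec()].
#' @param residual Residual intensity fraction left in the bleached zones.
#' @return List with `series` (an [image_stack()], `dim3 = "t"`), `rois`
#'   (a `frap_rois`), and `truth` (list: `t_s`, `area_by_frame_um2`,
#'   `filament_area_um2` per translocating filament, `n_translocating`).
#' @export
simulate_frap_series <- function(mask,
                                 belt_geometry = list(belt_width_um = 5,
                                                      axis = "x"),
                                 sliding = list(n_translocating = 5,
                                                speed_um_s = 0.02),
                                 n_frames = 31,
                                 calibration = NULL,
                                 seed = 1,
                                 filament_length_um = 4,
                                 thickness_um = 0.5,
                                 intensity = 100,
                                 background = 5,
                                 psf_sigma_um = 0.15,
                                 noise_poisson_scale = 1,
                                 noise_gaussian_sd = 2,
                                 residual = 0) {
  if (n_frames < 2) stop("`n_frames` must be at least 2", call. = FALSE)
  m <- as_mask_matrix(mask)
  mask_cal <- get_calibration(mask)
  if (is.null(calibration)) {
    calibration <- pixel_calibration(mask_cal$pixel_size_um,
                                     frame_interval_s = 10)
  }
  if (is.null(calibration$frame_interval_s)) {
    stop("calibration needs `frame_interval_s`", call. = FALSE)
  }
  px <- calibration$pixel_size_um
  belt_width <- belt_geometry$belt_width_um %||% 5
  axis <- belt_geometry$axis %||% "x"
  n_tr <- sliding$n_translocating %||% 0
  speed <- sliding$speed_um_s %||% 0.02
  n_static <- sliding$n_static %||% 12
  if (filament_length_um + thickness_um >= belt_width) {
    stop("translocating filaments must fit inside the belt", call. = FALSE)
  }

  rois <- define_frap_rois(as_cell_mask(m, calibration), axis = axis,
                           belt_width_um = belt_width)
  nx <- nrow(m); ny <- ncol(m)
  dt <- calibration$frame_interval_s
  times <- (seq_len(n_frames) - 1) * dt
  thick_px <- thickness_um / px

  with_seed(seed, {
    # static filaments along the belt stripe (perpendicular to `axis`)
    static_canvas <- matrix(0, nx, ny)
    belt_idx <- which(rois$belt)
    for (f in seq_len(n_static)) {
      idx <- belt_idx[sample.int(length(belt_idx), 1L)]
      i0 <- (idx - 1L) %% nx + 1L; j0 <- (idx - 1L) %/% nx + 1L
      theta <- if (axis == "x") pi / 2 else 0
      theta <- theta + stats::runif(1, -0.15, 0.15)
      tr <- trace_straight(rois$belt, px, (i0 - 0.5) * px, (j0 - 0.5) * px,
                           theta, belt_width * 2)
      if (is.null(tr)) next
      st <- stamp_polyline(nx, ny, tr$points / px + 0.5, tr$dirs, thick_px)
      if (is.null(st)) next
      static_canvas[st$idx] <- pmax(static_canvas[st$idx],
                                    intensity * st$coverage)
    }

    # translocating filaments: along `axis`, start centered in the belt
    cross_range <- {
      idx <- which(rois$belt, arr.ind = TRUE)
      cr <- if (axis == "x") (idx[, 2] - 0.5) * px else (idx[, 1] - 0.5) * px
      range(cr)
    }
    margin <- min(1.5, diff(cross_range) / 4)
    tr_cross <- if (n_tr > 0) {
      seq(cross_range[1] + margin, cross_range[2] - margin,
          length.out = n_tr) + stats::runif(n_tr, -0.3, 0.3)
    } else numeric(0)
    tr_dir <- rep(c(1, -1), length.out = n_tr)
    center_along <- rois$center_um

    # sliding filaments stop at the cell edge: per filament, the in-mask
    # interval of the along coordinate at its cross position bounds the
    # filament center
    center_bounds <- lapply(seq_len(n_tr), function(f) {
      jc <- pmin(pmax(round(tr_cross[f] / px + 0.5), 1),
                 if (axis == "x") ny else nx)
      line <- if (axis == "x") m[, jc] else m[jc, ]
      ic <- round(center_along / px + 0.5)
      lo <- ic; while (lo > 1 && line[lo - 1]) lo <- lo - 1
      hi <- ic; while (hi < length(line) && line[hi + 1]) hi <- hi + 1
      half <- filament_length_um / 2 + thickness_um
      c((lo - 0.5) * px + half, (hi - 0.5) * px - half)
    })

    theta_tr <- if (axis == "x") 0 else pi / 2
    frames <- array(0, c(nx, ny, n_frames))
    truth_area <- numeric(n_frames)
    fil_area <- numeric(n_tr)
    zones <- rois$bleach[[1]] | rois$bleach[[2]]

    for (k in seq_len(n_frames)) {
      canvas <- static_canvas
      tr_mask <- matrix(FALSE, nx, ny)
      for (f in seq_len(n_tr)) {
        shift <- tr_dir[f] * speed * times[k]
        b <- center_bounds[[f]]
        c_along <- min(max(center_along + shift, b[1]), b[2])
        x0 <- if (axis == "x") c_along else tr_cross[f]
        y0 <- if (axis == "x") tr_cross[f] else c_along
        tr <- trace_straight(m, px, x0, y0, theta_tr, filament_length_um)
        if (is.null(tr)) next
        st <- stamp_polyline(nx, ny, tr$points / px + 0.5, tr$dirs,
                             thick_px)
        if (is.null(st)) next
        canvas[st$idx] <- pmax(canvas[st$idx], intensity * st$coverage)
        on <- st$idx[st$coverage >= 0.5]
        tr_mask[on] <- TRUE
        if (k == 1) fil_area[f] <- length(on) * px^2
      }
      truth_area[k] <- sum(tr_mask & zones) * px^2

      if (residual > 0) canvas[zones] <- pmax(canvas[zones],
                                              residual * intensity)
      blurred <- gaussian_smooth(canvas, psf_sigma_um / px) + background
      noisy <- blurred
      if (noise_poisson_scale > 0) {
        noisy <- matrix(stats::rpois(length(blurred),
                                     blurred * noise_poisson_scale) /
                          noise_poisson_scale, nx, ny)
      }
      if (noise_gaussian_sd > 0) {
        noisy <- noisy + matrix(stats::rnorm(length(noisy), 0,
                                             noise_gaussian_sd), nx, ny)
      }
      noisy[noisy < 0] <- 0
      frames[, , k] <- noisy
    }

    list(series = image_stack(frames, calibration, channel = "tubulin",
                              dim3 = "t"),
         rois = rois,
         truth = list(t_s = times,
                      area_by_frame_um2 = truth_area,
                      filament_area_um2 = fil_area,
                      n_translocating = n_tr))
  })
}
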