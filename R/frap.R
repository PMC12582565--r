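#' Define FRAP belt and bleached-zone regions over a cell
#'
#' Splits a cell footprint into the unbleached "fluorescent belt" — a
#' central stripe of `belt_width_um` across the cell — and the two
#' photobleached zones on either side. The stripe runs perpendicular to
#' `axis`, so the two bleached zones sit at either end of the cell along
#' that axis, separated by the belt width (about 5 um by default).
#'
#' @param cell_mask A `cell_mask`.
#' @param axis `"x"` or `"y"`: the axis along which the bleached zones are
#'   separated.
#' @param belt_width_um Width of the unbleached belt (> 0, smaller than
#'   the cell extent along `axis`).
#' @param calibration Taken from the mask when omitted.
#' @return A `frap_rois`: list with logical matrices `belt`, `bleach`
#'   (list of the two zones), `cell`, plus `axis` and `calibration`. The
#'   belt and the two zones partition the cell mask exactly.
#' @export
define_frap_rois <- function(cell_mask, axis = c("x", "y"),
                             belt_width_um = 5, calibration = NULL) {
  axis <- match.arg(axis)
  stopifnot_scalar_pos(belt_width_um, "belt_width_um")
  calibration <- get_calibration(cell_mask, calibration)
  m <- as_mask_matrix(cell_mask)
  if (!any(m)) stop("cell mask is empty", call. = FALSE)
  px <- calibration$pixel_size_um
  idx <- which(m, arr.ind = TRUE)
  coord <- if (axis == "x") idx[, 1] else idx[, 2]
  coord_um <- (coord - 0.5) * px
  center <- mean(range(coord_um))
  along <- matrix(if (axis == "x") (row(m) - 0.5) * px
                  else (col(m) - 0.5) * px, nrow(m), ncol(m))
  belt <- m & abs(along - center) <= belt_width_um / 2
  z1 <- m & (along < center - belt_width_um / 2)
  z2 <- m & (along > center + belt_width_um / 2)
  if (!any(z1) || !any(z2)) {
    stop("belt covers the whole cell along the chosen axis", call. = FALSE)
  }
  structure(list(belt = belt, bleach = list(z1, z2), cell = m,
                 axis = axis, belt_width_um = belt_width_um,
                 center_um = center, calibration = calibration),
            class = "frap_rois")
}

#' @export
print.frap_rois <- function(x, ...) {
  px2 <- x$calibration$pixel_size_um^2
  cat(sprintf(
    "frap_rois: belt %.1f um^2, bleached zones %.1f / %.1f um^2 (%s axis)\n",
    sum(x$belt) * px2, sum(x$bleach[[1]]) * px2, sum(x$bleach[[2]]) * px2,
    x$axis))
  invisible(x)
}

#' Displaced MT area entering the bleached zones
#'
#' Quantifies MT sliding from a post-bleach time-lapse as the area of
#' high-signal MTs found inside the bleached zones at each time point —
#' fluorescent material there can only have moved in from the belt. Pixels
#' count as high-signal when they exceed a threshold chosen to mask out
#' background and low-signal MTs (presumed polymerizing ends); the
#' residual area at frame 0 (the first post-bleach frame) is subtracted
#' from every frame and the result floored at 0, so `area(0) = 0` by
#' construction. The headline readout is the area at the frame nearest
#' `readout_time_s` (default 300 s = 5 min of recovery).
#'
#' Threshold modes:
#' * `"belt_fraction"` (default): `belt_fraction` times the mean intensity
#'   of MT-positive belt pixels at frame 0 (MT-positive by IsoData within
#'   the belt). Anchoring to the belt makes the cut-off track the
#'   brightness of the unbleached MTs being slid.
#' * `"belt_mean_fraction"`: `belt_fraction` times the mean over *all*
#'   belt pixels at frame 0.
#' * `"isodata"`: IsoData over in-cell pixels of frame 0.
#' * `"fixed"`: `threshold_value`.
#'
#' @param series An [image_stack()] with `dim3 = "t"` (first frame =
#'   first post-bleach frame) or a z+t series already projected.
#' @param rois A [define_frap_rois()] result.
#' @param threshold_mode See above.
#' @param threshold_value Threshold for `"fixed"` mode.
#' @param belt_fraction Fraction for the belt-anchored modes.
#' @param readout_time_s Recovery time of the headline readout.
#' @return A `sliding_measure`: list with `per_frame` (data frame `frame`,
#'   `t_s`, `area_um2`, `area_norm` — the latter normalized to the total
#'   bleached-zone area), `readout_area_um2`, `readout_frame`,
#'   `readout_time_s`, `threshold`, and `truncated` (`TRUE` when the
#'   series ends before the requested readout time, in which case the last
#'   frame is used).
#' @export
displaced_mt_area <- function(series, rois,
                              threshold_mode = c("belt_fraction",
                                                 "belt_mean_fraction",
                                                 "isodata", "fixed"),
                              threshold_value = NULL,
                              belt_fraction = 0.5,
                              readout_time_s = 300) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(series, "image_stack"))
  if (series$dim3 != "t") stop("series must be a time-lapse", call. = FALSE)
  stopifnot(inherits(rois, "frap_rois"))
  px2 <- series$calibration$pixel_size_um^2
  times <- stack_times(series)
  f0 <- series$pixels[, , 1]

  thr <- switch(threshold_mode,
    belt_fraction = {
      belt_thr <- isodata_value(f0[rois$belt])
      belt_fraction * mean(f0[rois$belt & (f0 >= belt_thr)])
    },
    belt_mean_fraction = belt_fraction * mean(f0[rois$belt]),
    isodata = isodata_value(f0[rois$cell]),
    fixed = {
      if (is.null(threshold_value)) {
        stop("fixed mode needs `threshold_value`", call. = FALSE)
      }
      threshold_value
    })

  zones <- rois$bleach[[1]] | rois$bleach[[2]]
  raw <- vapply(seq_along(times), function(k) {
    sum(series$pixels[, , k][zones] >= thr) * px2
  }, numeric(1))
  area <- pmax(raw - raw[1], 0)

  truncated <- max(times) < readout_time_s
  readout_frame <- if (truncated) length(times) else
    which.min(abs(times - readout_time_s))
  zone_area <- sum(zones) * px2
  per_frame <- data.frame(frame = seq_along(times) - 1L, t_s = times,
                          area_um2 = area, area_norm = area / zone_area)
  structure(list(per_frame = per_frame,
                 readout_area_um2 = area[readout_frame],
                 readout_frame = readout_frame - 1L,
                 readout_time_s = times[readout_frame],
                 threshold = thr, threshold_mode = threshold_mode,
                 zone_area_um2 = zone_area,
                 belt_area_um2 = sum(rois$belt) * px2,
                 truncated = truncated),
            class = "sliding_measure")
}

#' @export
print.sliding_measure <- function(x, ...) {
  cat(sprintf(
    "MT sliding: displaced area %.2f um^2 at %g s (threshold %.3g%s)\n",
    x$readout_area_um2, x$readout_time_s, x$threshold,
    if (x$truncated) ", series truncated" else ""))
  invisible(x)
}

#' @export
plot.sliding_measure <- function(x, ...) {
  plot(x$per_frame$t_s, x$per_frame$area_um2, type = "b",
                 xlab = "time after bleach (s)",
                 ylab = expression("displaced MT area (" * mu * m^2 * ")"),
                 ...)
  invisible(x)
}
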