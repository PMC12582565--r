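#' Pixel and time calibration of an acquisition
#'
#' Bundles the physical calibration every quantification in this package
#' depends on: the lateral pixel size, the frame interval of a time-lapse,
#' and the axial step of a z-stack. All values must be strictly positive
#' where present.
#'
#' @param pixel_size_um Lateral size of one pixel in micrometers.
#' @param frame_interval_s Time between frames in seconds, for time-lapses;
#'   `NULL` for single images.
#' @param z_step_um Axial distance between optical slices in micrometers;
#'   `NULL` for 2D images.
#' @return An object of class `pixel_calibration`.
#' @seealso [calibration_preset()] for acquisition-matched presets.
#' @export
#' @examples
#' pixel_calibration(0.1, frame_interval_s = 10)
pixel_calibration <- function(pixel_size_um = 0.1, frame_interval_s = NULL,
                              z_step_um = NULL) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  if (!is.null(frame_interval_s)) {
    stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  }
  if (!is.null(z_step_um)) stopifnot_scalar_pos(z_step_um, "z_step_um")
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 z_step_um = z_step_um),
            class = "pixel_calibration")
}

#' Acquisition-matched calibration presets
#'
#' Convenience constructors for the three acquisition regimes the analyses
#' target: fixed-cell imaging (`"image"`), belt-FRAP live imaging
#' (`"frap"`, 10 s frame interval, 0.4 um z-step), and fast fiducial-mark
#' imaging (`"suntag"`, 0.1 s frame interval, single plane).
#'
#' @param preset One of `"image"`, `"frap"`, `"suntag"`.
#' @param pixel_size_um Lateral pixel size; the default 0.1 um is the
#'   generator default, not an instrument constant.
#' @return A [pixel_calibration()] object.
#' @export
calibration_preset <- function(preset = c("image", "frap", "suntag"),
                               pixel_size_um = 0.1) {
  preset <- match.arg(preset)
  switch(preset,
    image  = pixel_calibration(pixel_size_um),
    frap   = pixel_calibration(pixel_size_um, frame_interval_s = 10,
                               z_step_um = 0.4),
    suntag = pixel_calibration(pixel_size_um, frame_interval_s = 0.1)
  )
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat("pixel calibration:", x$pixel_size_um, "um/px")
  if (!is.null(x$frame_interval_s)) cat(",", x$frame_interval_s, "s/frame")
  if (!is.null(x$z_step_um)) cat(",", x$z_step_um, "um z-step")
  cat("\n")
  invisible(x)
}

#' Analysis constants for peripheral MT quantification
#'
#' One container for every numeric constant of the standard analysis:
#' band widths, angle bin width, displacement window and bin width, the
#' stationary/motile displacement thresholds, the FRAP readout time, and
#' the coherence cut-off below which an orientation estimate is treated as
#' inconclusive.
#'
#' Defaults are the published procedure: directionality is binned within
#' the outer 1 um of the cell in 10-degree bins; peripheral intensity uses
#' the outer 2 um; fiducial-mark displacements are measured over 5 s
#' windows, binned at 0.05 um, and called stationary below 0.15 um and
#' motile above 0.3 um per 5 s (values at a threshold are intermediate);
#' FRAP sliding is read out 300 s (5 min) after photobleaching. The
#' coherence minimum (default 0.2) is an implementation constant, not a
#' published value.
#'
#' @param band_hist_um Peripheral band width for directionality histograms.
#' @param band_intensity_um Peripheral band width for intensity readouts.
#' @param angle_bin_deg Angle bin width; must divide 90.
#' @param displacement_window_s Displacement window length in seconds.
#' @param displacement_bin_um Displacement histogram bin width.
#' @param stationary_max_um Displacements strictly below this (per window)
#'   are stationary.
#' @param motile_min_um Displacements strictly above this (per window) are
#'   motile.
#' @param frap_readout_time_s Recovery time at which FRAP displaced area is
#'   reported.
#' @param coherence_min Minimum structure-tensor coherence for a pixel's
#'   orientation to count as conclusive.
#' @return An object of class `analysis_parameters`.
#' @export
#' @examples
#' analysis_parameters()
analysis_parameters <- function(band_hist_um = 1,
                                band_intensity_um = 2,
                                angle_bin_deg = 10,
                                displacement_window_s = 5,
                                displacement_bin_um = 0.05,
                                stationary_max_um = 0.15,
                                motile_min_um = 0.3,
                                frap_readout_time_s = 300,
                                coherence_min = 0.2) {
  stopifnot_scalar_pos(band_hist_um, "band_hist_um")
  stopifnot_scalar_pos(band_intensity_um, "band_intensity_um")
  stopifnot_scalar_pos(angle_bin_deg, "angle_bin_deg")
  if (abs(90 / angle_bin_deg - round(90 / angle_bin_deg)) > 1e-9) {
    stop("`angle_bin_deg` must divide 90", call. = FALSE)
  }
  stopifnot_scalar_pos(displacement_window_s, "displacement_window_s")
  stopifnot_scalar_pos(displacement_bin_um, "displacement_bin_um")
  stopifnot_scalar_pos(stationary_max_um, "stationary_max_um")
  stopifnot_scalar_pos(motile_min_um, "motile_min_um")
  if (stationary_max_um >= motile_min_um) {
    stop("`stationary_max_um` must be smaller than `motile_min_um`",
         call. = FALSE)
  }
  stopifnot_scalar_pos(frap_readout_time_s, "frap_readout_time_s")
  if (!is.numeric(coherence_min) || coherence_min < 0 || coherence_min > 1) {
    stop("`coherence_min` must be in [0, 1]", call. = FALSE)
  }
  structure(list(band_hist_um = band_hist_um,
                 band_intensity_um = band_intensity_um,
                 angle_bin_deg = angle_bin_deg,
                 displacement_window_s = displacement_window_s,
                 displacement_bin_um = displacement_bin_um,
                 stationary_max_um = stationary_max_um,
                 motile_min_um = motile_min_um,
                 frap_readout_time_s = frap_readout_time_s,
                 coherence_min = coherence_min),
            class = "analysis_parameters")
}

#' @export
print.analysis_parameters <- function(x, ...) {
  cat("Peripheral MT analysis parameters\n")
  cat(sprintf("  directionality band : outer %g um, %g deg bins\n",
              x$band_hist_um, x$angle_bin_deg))
  cat(sprintf("  intensity band      : outer %g um\n", x$band_intensity_um))
  cat(sprintf("  displacement        : %g s windows, %g um bins\n",
              x$displacement_window_s, x$displacement_bin_um))
  cat(sprintf("  motility thresholds : stationary < %g, motile > %g um\n",
              x$stationary_max_um, x$motile_min_um))
  cat(sprintf("  FRAP readout        : %g s\n", x$frap_readout_time_s))
  cat(sprintf("  coherence minimum   : %g\n", x$coherence_min))
  invisible(x)
}
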