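#' Calibrated image stack
#'
#' A thin container for grayscale pixel data plus its physical calibration.
#' `pixels` is a numeric matrix (2D image, indexed `[x, y]`) or 3D array
#' whose third dimension is either optical slices (`dim3 = "z"`) or time
#' points (`dim3 = "t"`). Intensities must be finite and non-negative.
#'
#' @param pixels Numeric matrix or 3D array of intensities.
#' @param calibration A [pixel_calibration()].
#' @param channel Optional channel label.
#' @param dim3 Meaning of the third array dimension: `"none"`, `"z"`, `"t"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, calibration, channel = "",
                        dim3 = c("none", "z", "t")) {
  dim3 <- match.arg(dim3)
  if (!is.numeric(pixels)) stop("`pixels` must be numeric", call. = FALSE)
  nd <- length(dim(pixels))
  if (nd == 0 || nd > 3) stop("`pixels` must be 2D or 3D", call. = FALSE)
  if (nd == 2 && dim3 != "none") {
    stop("2D pixels cannot carry a z or t dimension", call. = FALSE)
  }
  if (nd == 3 && dim3 == "none") {
    stop("3D pixels need `dim3` of \"z\" or \"t\"", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    stop("image intensities must be finite", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("image intensities must be non-negative", call. = FALSE)
  }
  if (!inherits(calibration, "pixel_calibration")) {
    stop("`calibration` must be a pixel_calibration", call. = FALSE)
  }
  if (dim3 == "z" && is.null(calibration$z_step_um)) {
    stop("z-stacks need `z_step_um` in the calibration", call. = FALSE)
  }
  if (dim3 == "t" && is.null(calibration$frame_interval_s)) {
    stop("time series need `frame_interval_s` in the calibration",
         call. = FALSE)
  }
  structure(list(pixels = pixels, calibration = calibration,
                 channel = channel, dim3 = dim3),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_stack %s: %d x %d px", x$dim3, d[1], d[2]))
  if (length(d) == 3) cat(sprintf(" x %d %s", d[3], x$dim3))
  cat(sprintf(" @ %g um/px", x$calibration$pixel_size_um))
  if (nzchar(x$channel)) cat(sprintf(" [%s]", x$channel))
  cat("\n")
  invisible(x)
}

#' Number of frames / slices and their physical coordinates
#' @param x An `image_stack`.
#' @return For `stack_times`, a vector of frame times in seconds; for
#'   `stack_z`, slice depths in micrometers (first slice at 0).
#' @export
stack_times <- function(x) {
  stopifnot(inherits(x, "image_stack"), x$dim3 == "t")
  (seq_len(dim(x$pixels)[3]) - 1) * x$calibration$frame_interval_s
}

#' @rdname stack_times
#' @export
stack_z <- function(x) {
  stopifnot(inherits(x, "image_stack"), x$dim3 == "z")
  (seq_len(dim(x$pixels)[3]) - 1) * x$calibration$z_step_um
}

#' Write / read an image stack as multi-page TIFF
#'
#' Pages are written as 32-bit float TIFF. Because baseline TIFF stores
#' floats in `[0, 1]`, intensities are divided by a scale factor (default:
#' the stack maximum) that is recorded, together with the calibration and
#' the third-dimension semantics (z or t), in a YAML sidecar
#' `<path>.yaml`; reading reverses the scaling.
#'
#' @param x An `image_stack`.
#' @param path Output TIFF path.
#' @param scale Intensity scale factor; stored pixel = intensity / scale.
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns an `image_stack`.
#' @export
write_image_tiff <- function(x, path, scale = NULL) {
  stopifnot(inherits(x, "image_stack"))
  px <- x$pixels
  if (is.null(scale)) scale <- max(px, 1e-12)
  stopifnot_scalar_pos(scale, "scale")
  if (length(dim(px)) == 2) px <- array(px, c(dim(px), 1L))
  # tiff expects [row, col] = [y, x]: transpose each page
  pages <- lapply(seq_len(dim(px)[3]),
                  function(k) t(px[, , k]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  meta <- list(scale = scale, dim3 = x$dim3, channel = x$channel,
               pixel_size_um = x$calibration$pixel_size_um,
               frame_interval_s = x$calibration$frame_interval_s,
               z_step_um = x$calibration$z_step_um)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) {
    stop("missing sidecar ", meta_path, call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(p) t(as.matrix(p)) * meta$scale,
                matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  cal <- pixel_calibration(meta$pixel_size_um,
                           frame_interval_s = meta$frame_interval_s,
                           z_step_um = meta$z_step_um)
  dim3 <- meta$dim3
  if (dim(arr)[3] == 1L && dim3 == "none") {
    arr <- arr[, , 1]
  }
  image_stack(arr, cal, channel = meta$channel %||% "", dim3 = dim3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
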