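#' Directionality histogram within a peripheral distance band
#'
#' Bins border-relative MT angles of all conclusive pixels whose distance
#' to the border falls in `band` into angle bins covering `[0, 90]`
#' (default nine 10-degree bins). Bin edges are half-open,
#' `[0,10), [10,20), ...`, with the last bin closed at 90 so a perfectly
#' perpendicular pixel is counted; an angle exactly on an interior edge
#' goes to the upper bin. The 0-10 bin is the "parallel" bin.
#'
#' @param angles An [angle_to_border()] `angle_map` (or numeric matrix of
#'   angles with `NA` for invalid pixels).
#' @param geom The matching [compute_border_geometry()].
#' @param band Distance band `c(lo, hi)` in micrometers, half-open
#'   `[lo, hi)`; default the outer 1 um.
#' @param bin_width_deg Angle bin width; must divide 90.
#' @param cell_id Optional label carried into summaries.
#' @return A `directionality_histogram`: data frame with columns `bin_lo`,
#'   `bin_hi`, `count`, `fraction`, plus attributes `band`, `n_pixels`,
#'   `cell_id`. With zero pixels in the band, counts are 0, fractions are
#'   `NA`, and attribute `empty` is `TRUE` (no error is raised).
#' @export
bin_directionality <- function(angles, geom, band = c(0, 1),
                               bin_width_deg = 10, cell_id = NA) {
  stopifnot(inherits(geom, "border_geometry"))
  if (length(band) != 2L || band[2] <= band[1] || band[1] < 0) {
    stop("`band` must be c(lo, hi) with 0 <= lo < hi", call. = FALSE)
  }
  if (abs(90 / bin_width_deg - round(90 / bin_width_deg)) > 1e-9) {
    stop("`bin_width_deg` must divide 90", call. = FALSE)
  }
  a <- unclass(angles)
  sel <- !is.na(a) & !is.na(geom$distance_um) &
    geom$distance_um >= band[1] & geom$distance_um < band[2]
  vals <- a[sel]
  nb <- as.integer(round(90 / bin_width_deg))
  idx <- pmin(floor(vals / bin_width_deg) + 1L, nb)  # 90 -> last bin
  counts <- tabulate(idx, nbins = nb)
  n <- length(vals)
  out <- data.frame(bin_lo = (seq_len(nb) - 1) * bin_width_deg,
                    bin_hi = seq_len(nb) * bin_width_deg,
                    count = counts,
                    fraction = if (n > 0) counts / n else rep(NA_real_, nb))
  structure(out, band = band, n_pixels = n, cell_id = cell_id,
            empty = n == 0L,
            class = c("directionality_histogram", "data.frame"))
}

#' @export
print.directionality_histogram <- function(x, ...) {
  band <- attr(x, "band")
  cat(sprintf("directionality histogram, band [%g, %g) um, n = %d px\n",
              band[1], band[2], attr(x, "n_pixels")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.directionality_histogram <- function(x, main = NULL, ...) {
  band <- attr(x, "band")
  if (is.null(main)) {
    main <- sprintf("MT directionality, %g-%g um from border",
                    band[1], band[2])
  }
  graphics::barplot(x$fraction,
                    names.arg = sprintf("%g-%g", x$bin_lo, x$bin_hi),
                    xlab = "angle to border (deg)", ylab = "fraction",
                    main = main, ...)
  invisible(x)
}

#' Directionality as a function of distance from the cell border
#'
#' One [bin_directionality()] histogram per consecutive distance band
#' `[e1, e2), [e2, e3), ...`. Bands are disjoint, so their pixel counts
#' sum to the number of conclusive pixels within the outermost edge.
#'
#' @param angles An `angle_map`.
#' @param geom The matching `border_geometry`.
#' @param band_edges_um Increasing band edges; default `0:5` um.
#' @param bin_width_deg Angle bin width.
#' @param cell_id Optional label.
#' @return List of `directionality_histogram`, named `"[lo,hi)"`.
#' @export
directionality_vs_distance <- function(angles, geom, band_edges_um = 0:5,
                                       bin_width_deg = 10, cell_id = NA) {
  if (length(band_edges_um) < 2L || any(diff(band_edges_um) <= 0)) {
    stop("`band_edges_um` must be strictly increasing", call. = FALSE)
  }
  out <- lapply(seq_len(length(band_edges_um) - 1L), function(k) {
    bin_directionality(angles, geom,
                       band = band_edges_um[k + c(0, 1)],
                       bin_width_deg = bin_width_deg, cell_id = cell_id)
  })
  names(out) <- sprintf("[%g,%g)", head(band_edges_um, -1),
                        band_edges_um[-1])
  out
}

#' Pool per-cell directionality histograms
#'
#' Population summaries are reported two ways, because either reading of
#' "summarized over cells" is defensible: `"pixel"` pooling sums raw pixel
#' counts across cells (cells with more detectable MT pixels weigh more,
#' matching legends that report total pixel numbers), while `"cell"`
#' pooling averages per-cell fractions so every cell weighs equally.
#'
#' @param hists List of `directionality_histogram` (same bins and band).
#' @param weights `"pixel"` or `"cell"`.
#' @return A `directionality_histogram` with pooled counts/fractions (for
#'   `"cell"` weighting, `count` is the summed counts but `fraction` is
#'   the unweighted mean of per-cell fractions).
#' @export
pool_directionality <- function(hists, weights = c("pixel", "cell")) {
  weights <- match.arg(weights)
  stopifnot(length(hists) >= 1L)
  counts <- Reduce(`+`, lapply(hists, function(h) h$count))
  n <- sum(vapply(hists, function(h) attr(h, "n_pixels"), integer(1)))
  frac <- if (weights == "pixel") {
    if (n > 0) counts / n else rep(NA_real_, length(counts))
  } else {
    fr <- vapply(hists, function(h) h$fraction,
                 numeric(nrow(hists[[1]])))
    rowMeans(fr, na.rm = TRUE)
  }
  out <- data.frame(bin_lo = hists[[1]]$bin_lo, bin_hi = hists[[1]]$bin_hi,
                    count = counts, fraction = frac)
  structure(out, band = attr(hists[[1]], "band"), n_pixels = n,
            cell_id = sprintf("pooled_%s", weights), empty = n == 0L,
            class = c("directionality_histogram", "data.frame"))
}

#' One-call directionality analysis of a single cell
#'
#' Convenience wrapper chaining the standard analysis: optional
#' Richardson-Lucy deconvolution, thresholding (`"perfect"` per-cell
#' peripheral IsoData, `"isodata"` whole-cell, or `"fixed"`), structure
#' tensor orientation, border geometry, border-relative angles, and the
#' peripheral histogram.
#'
#' @param image An [image_stack()] (2D).
#' @param mask A `cell_mask`.
#' @param threshold_mode `"perfect"`, `"isodata"`, or `"fixed"`.
#' @param threshold_value Threshold for `"fixed"` mode.
#' @param deconvolve If `TRUE` (default), run RL deconvolution first, as
#'   in the standard conditioning chain.
#' @param psf_sigma_um,rl_iterations Deconvolution settings.
#' @param params An [analysis_parameters()].
#' @param cell_id Optional label.
#' @return List: `histogram` (outer band), `by_distance` (list of
#'   histograms over 1 um bands to 5 um), `angles`, `field`, `geometry`,
#'   `threshold`.
#' @export
directionality_analysis <- function(image, mask,
                                    threshold_mode = c("perfect", "isodata",
                                                       "fixed"),
                                    threshold_value = NULL,
                                    deconvolve = TRUE,
                                    psf_sigma_um = 0.15,
                                    rl_iterations = 30,
                                    params = analysis_parameters(),
                                    cell_id = NA) {
  threshold_mode <- match.arg(threshold_mode)
  if (deconvolve) {
    image <- richardson_lucy_deconvolve(image, psf_sigma_um, rl_iterations)
  }
  thr <- switch(threshold_mode,
    perfect = per_cell_perfect_threshold(image, mask,
                                         band_width_um = params$band_hist_um),
    isodata = isodata_threshold(image, mask),
    fixed = fixed_threshold(image, mask, threshold_value))
  geom <- compute_border_geometry(mask)
  field <- compute_orientation_field(image, thr,
                                     coherence_min = params$coherence_min,
                                     cell_mask = mask)
  ang <- angle_to_border(field, geom)
  hist1 <- bin_directionality(ang, geom, band = c(0, params$band_hist_um),
                              bin_width_deg = params$angle_bin_deg,
                              cell_id = cell_id)
  byd <- directionality_vs_distance(ang, geom,
                                    bin_width_deg = params$angle_bin_deg,
                                    cell_id = cell_id)
  list(histogram = hist1, by_distance = byd, angles = ang, field = field,
       geometry = geom, threshold = thr)
}
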