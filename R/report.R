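#' Build a machine-readable report bundle from analysis outputs
#'
#' Writes the run's results into `out_dir` as CSV tables, PNG figures,
#' and one `report.json` summarizing parameters and per-cell metrics.
#' The JSON is built from the CSV tables after they are written, with
#' deterministic ordering and number formatting, so re-running the report
#' on unchanged inputs reproduces `report.json` byte for byte, and every
#' figure can be regenerated from the CSVs alone.
#'
#' @param out_dir Output directory (created if absent).
#' @param directionality Optional list of per-cell
#'   `directionality_histogram`s.
#' @param motility Optional `motility_summary`.
#' @param displacement_bins Optional [bin_displacements()] result.
#' @param frap Optional list of `sliding_measure`s (named by cell).
#' @param intensity Optional data frame of per-cell intensity readouts
#'   (e.g. [depletion_fold()] output).
#' @param comparison Optional `group_comparison`.
#' @param params An [analysis_parameters()].
#' @param figures Write PNG figures as well (default `TRUE`).
#' @return Path of `report.json`, invisibly; stops if every input is
#'   `NULL`, naming what is missing.
#' @export
build_report <- function(out_dir,
                         directionality = NULL,
                         motility = NULL,
                         displacement_bins = NULL,
                         frap = NULL,
                         intensity = NULL,
                         comparison = NULL,
                         params = analysis_parameters(),
                         figures = TRUE) {
  inputs <- list(directionality = directionality, motility = motility,
                 displacement_bins = displacement_bins, frap = frap,
                 intensity = intensity, comparison = comparison)
  if (all(vapply(inputs, is.null, logical(1)))) {
    stop("nothing to report: supply at least one of ",
         paste(names(inputs), collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  num <- function(x) round(x, 10)  # stable decimal representation

  if (!is.null(directionality)) {
    tab <- do.call(rbind, lapply(directionality, function(h) {
      band <- attr(h, "band")
      data.frame(cell_id = attr(h, "cell_id"),
                 band_lo = band[1], band_hi = band[2],
                 bin_lo = h$bin_lo, bin_hi = h$bin_hi,
                 count = h$count, fraction = num(h$fraction))
    }))
    f <- file.path(out_dir, "directionality.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(motility)) {
    f <- file.path(out_dir, "motility.csv")
    m <- as.data.frame(motility)
    m[c("f_stationary", "f_intermediate", "f_motile")] <-
      lapply(m[c("f_stationary", "f_intermediate", "f_motile")], num)
    utils::write.csv(m, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(displacement_bins)) {
    f <- file.path(out_dir, "displacement_bins.csv")
    pc <- displacement_bins$per_cell
    pc$pct <- num(pc$pct)
    utils::write.csv(pc, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(frap)) {
    tab <- do.call(rbind, lapply(names(frap), function(id) {
      data.frame(cell_id = id, frap[[id]]$per_frame,
                 readout_area_um2 = num(frap[[id]]$readout_area_um2))
    }))
    tab$area_um2 <- num(tab$area_um2); tab$area_norm <- num(tab$area_norm)
    f <- file.path(out_dir, "frap_sliding.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(intensity)) {
    f <- file.path(out_dir, "intensity.csv")
    utils::write.csv(as.data.frame(intensity), f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(comparison)) {
    if (!is.null(comparison$per_bin)) {
      f <- file.path(out_dir, "comparison_per_bin.csv")
      pb <- comparison$per_bin
      pb[] <- lapply(pb, num)
      utils::write.csv(pb, f, row.names = FALSE)
      written <- c(written, f)
    }
  }

  # JSON built from the just-written CSVs so report.json is reproducible
  # from the tables alone.
  json <- list(parameters = unclass(params))
  for (f in sort(written)) {
    key <- sub("\\.csv$", "", basename(f))
    json[[key]] <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  if (!is.null(comparison) && !is.null(comparison$ks)) {
    json$ks_test <- list(statistic = num(comparison$ks$statistic),
                         p = num(comparison$ks$p))
  }
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  if (figures) {
    if (!is.null(directionality)) {
      grDevices::png(file.path(out_dir, "directionality.png"),
                     width = 700, height = 500)
      plot(pool_directionality(directionality))
      grDevices::dev.off()
    }
    if (!is.null(displacement_bins)) {
      grDevices::png(file.path(out_dir, "displacements.png"),
                     width = 700, height = 500)
      pop <- displacement_bins$population
      graphics::barplot(pop$mean_pct,
                        names.arg = sprintf("%.2f", pop$bin_lo),
                        xlab = "5-s displacement (um)",
                        ylab = "% of windows (mean over cells)")
      grDevices::dev.off()
    }
    if (!is.null(frap)) {
      grDevices::png(file.path(out_dir, "frap_sliding.png"),
                     width = 700, height = 500)
      first <- frap[[1]]$per_frame
      plot(first$t_s, first$area_um2, type = "n",
           xlab = "time after bleach (s)",
           ylab = "displaced MT area (um^2)",
           ylim = c(0, max(vapply(frap, function(s)
             max(s$per_frame$area_um2), numeric(1))) * 1.05))
      for (s in frap) lines(s$per_frame$t_s, s$per_frame$area_um2)
      grDevices::dev.off()
    }
  }
  invisible(json_path)
}

#' Color-coded angle overlay
#'
#' Writes a PNG in which every conclusive MT pixel is colored by its angle
#' to the border: blue parallel (0 degrees) through red perpendicular
#' (90 degrees); non-MT pixels are white, the off-cell area light gray.
#'
#' @param angles An [angle_to_border()] `angle_map`.
#' @param geom The matching `border_geometry`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_angle_overlay <- function(angles, geom, path) {
  a <- unclass(angles)
  cols <- grDevices::colorRampPalette(c("blue", "cyan", "yellow",
                                        "red"))(91)
  img <- matrix("white", nrow(a), ncol(a))
  img[!geom$mask] <- "grey90"
  ok <- !is.na(a)
  img[ok] <- cols[round(a[ok]) + 1L]
  grDevices::png(path, width = ncol(a), height = nrow(a))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(t(img)), 0, 0, 1, 1,
                        interpolate = FALSE)
  grDevices::dev.off()
  invisible(path)
}
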