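#' Read particle tracks from a CSV export
#'
#' Reads a spot-tracker CSV export into a `track_set`. The file must
#' contain a track identifier, a time column and x/y position columns;
#' column names are mapped through `schema`, and positions/times are
#' converted to micrometers and seconds according to `units`. Rows are
#' grouped by track and sorted by time.
#'
#' @param path CSV file path.
#' @param schema Named list mapping the canonical names `track_id`, `t`,
#'   `x`, `y` (and optionally `cell_id`, `intensity`) to the file's column
#'   names. Defaults to the package's own schema
#'   (`track_id,t_s,x_um,y_um`).
#' @param units List with `position` (`"um"`, `"nm"`, `"mm"`) and `time`
#'   (`"s"`, `"ms"`, `"min"`).
#' @return A `track_set` data frame with columns `track_id`, `t_s`,
#'   `x_um`, `y_um` and any mapped extras.
#' @export
read_tracks_csv <- function(path,
                            schema = list(track_id = "track_id", t = "t_s",
                                          x = "x_um", y = "y_um"),
                            units = list(position = "um", time = "s")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "t", "x", "y")
  missing_map <- setdiff(required, names(schema))
  if (length(missing_map)) {
    stop("schema must map columns: ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(unlist(schema[required]), names(raw))
  if (length(missing_cols)) {
    stop("missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pos_f <- switch(units$position %||% "um",
                  um = 1, nm = 1e-3, mm = 1e3,
                  stop("unknown position unit", call. = FALSE))
  t_f <- switch(units$time %||% "s",
                s = 1, ms = 1e-3, min = 60,
                stop("unknown time unit", call. = FALSE))
  out <- data.frame(track_id = raw[[schema$track_id]],
                    t_s = raw[[schema$t]] * t_f,
                    x_um = raw[[schema$x]] * pos_f,
                    y_um = raw[[schema$y]] * pos_f)
  for (extra in c("cell_id", "intensity")) {
    if (!is.null(schema[[extra]]) && schema[[extra]] %in% names(raw)) {
      out[[extra]] <- raw[[schema[[extra]]]]
    }
  }
  if (anyDuplicated(out[c("track_id", "t_s")])) {
    stop("duplicate (track_id, time) rows in track file", call. = FALSE)
  }
  out <- out[order(out$track_id, out$t_s), , drop = FALSE]
  rownames(out) <- NULL
  n_per <- table(out$track_id)
  if (any(n_per < 2)) {
    out <- out[!(out$track_id %in% names(n_per)[n_per < 2]), ,
               drop = FALSE]
  }
  class(out) <- c("track_set", "data.frame")
  out
}

#' Resample tracks onto a common time grid
#'
#' Places each track on the grid `t0, t0 + dt, t0 + 2 dt, ...` (with `t0`
#' the track's first time point) by nearest-sample selection: a grid point
#' takes the sample closest in time if one lies within `dt/2`, and is
#' otherwise left absent. Gaps are never interpolated. Tracks reduced
#' below two grid samples are dropped (their ids are recorded in the
#' `dropped` attribute).
#'
#' @param tracks A `track_set`.
#' @param dt_target_s Grid spacing in seconds (> 0).
#' @return A `track_set` on the grid, with attribute `dropped`.
#' @export
normalize_tracks <- function(tracks, dt_target_s) {
  stopifnot_scalar_pos(dt_target_s, "dt_target_s")
  tr <- as.data.frame(tracks)
  pieces <- lapply(split(tr, tr$track_id), function(d) {
    d <- d[order(d$t_s), , drop = FALSE]
    t0 <- d$t_s[1]
    grid <- seq(t0, max(d$t_s) + dt_target_s / 4, by = dt_target_s)
    pick <- vapply(grid, function(tg) {
      k <- which.min(abs(d$t_s - tg))
      if (abs(d$t_s[k] - tg) <= dt_target_s / 2 + 1e-9) k else NA_integer_
    }, integer(1))
    keep <- !is.na(pick)
    if (sum(keep) < 2L) return(NULL)
    out <- d[pick[keep], , drop = FALSE]
    out$t_s <- grid[keep]
    out
  })
  dropped <- names(pieces)[vapply(pieces, is.null, logical(1))]
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(out) <- NULL
  structure(out, dropped = dropped,
            class = c("track_set", "data.frame"))
}

#' Segment tracks into windowed displacements
#'
#' Cuts each track into consecutive time windows of `window_s` seconds
#' (default the published 5 s) and computes, per window, the net Euclidean
#' displacement between the positions at the window start and end —
#' displacement, not path length. Windows missing either endpoint (gaps)
#' are skipped. Each record is classified against the resolution-limit
#' thresholds: *stationary* strictly below `stationary_max_um`, *motile*
#' strictly above `motile_min_um`, *intermediate* otherwise (values at a
#' threshold are intermediate).
#'
#' @param tracks A `track_set`, already on a regular grid (see
#'   [normalize_tracks()]).
#' @param window_s Window length in seconds.
#' @param mode `"nonoverlapping"` (default; windows tile the track) or
#'   `"sliding"` (a window starts at every sample).
#' @param params An [analysis_parameters()] (thresholds).
#' @return Data frame of class `displacement_records`: `track_id`,
#'   `cell_id` (if present), `window_start_s`, `displacement_um`, `class`.
#' @export
five_second_displacements <- function(tracks, window_s = 5,
                                      mode = c("nonoverlapping", "sliding"),
                                      params = analysis_parameters()) {
  mode <- match.arg(mode)
  stopifnot_scalar_pos(window_s, "window_s")
  tr <- as.data.frame(tracks)
  has_cell <- "cell_id" %in% names(tr)
  tol <- 1e-6
  pieces <- lapply(split(tr, tr$track_id), function(d) {
    d <- d[order(d$t_s), , drop = FALSE]
    t0 <- d$t_s[1]
    starts <- if (mode == "nonoverlapping") {
      seq(t0, max(d$t_s) - window_s + tol, by = window_s)
    } else {
      d$t_s[d$t_s <= max(d$t_s) - window_s + tol]
    }
    if (!length(starts)) return(NULL)
    i0 <- match_time(d$t_s, starts, tol)
    i1 <- match_time(d$t_s, starts + window_s, tol)
    ok <- !is.na(i0) & !is.na(i1)
    if (!any(ok)) return(NULL)
    disp <- sqrt((d$x_um[i1[ok]] - d$x_um[i0[ok]])^2 +
                 (d$y_um[i1[ok]] - d$y_um[i0[ok]])^2)
    data.frame(track_id = d$track_id[1],
               cell_id = if (has_cell) d$cell_id[1] else "all",
               window_start_s = starts[ok],
               displacement_um = disp)
  })
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(track_id = integer(0), cell_id = character(0),
                      window_start_s = numeric(0),
                      displacement_um = numeric(0))
  }
  rownames(out) <- NULL
  out$class <- classify_displacement(out$displacement_um, params)
  class(out) <- c("displacement_records", "data.frame")
  out
}

match_time <- function(have, want, tol) {
  idx <- findInterval(want + tol, c(have, Inf))
  idx[idx < 1] <- NA
  hit <- !is.na(idx) & abs(have[pmax(idx, 1)] - want) <= tol
  ifelse(hit, idx, NA_integer_)
}

classify_displacement <- function(d, params = analysis_parameters()) {
  cls <- rep("intermediate", length(d))
  cls[d < params$stationary_max_um] <- "stationary"
  cls[d > params$motile_min_um] <- "motile"
  factor(cls, levels = c("stationary", "intermediate", "motile"))
}

#' Bin windowed displacements into per-cell percentage histograms
#'
#' Displacements are binned at `bin_width_um` intervals (default the
#' published 0.05 um), half-open `[0, 0.05), [0.05, 0.10), ...`, and the
#' percentage of each cell's distribution falling in each bin is computed;
#' the population summary reports mean and SEM per bin across cells.
#'
#' @param records A `displacement_records` data frame.
#' @param bin_width_um Bin width (> 0).
#' @param max_um Upper edge of the last bin; default covers the data.
#' @return List with `per_cell` (data frame `cell_id`, `bin_lo`, `bin_hi`,
#'   `count`, `pct`) and `population` (`bin_lo`, `bin_hi`, `mean_pct`,
#'   `sem_pct`, `n_cells`).
#' @export
bin_displacements <- function(records, bin_width_um = 0.05, max_um = NULL) {
  stopifnot_scalar_pos(bin_width_um, "bin_width_um")
  rec <- as.data.frame(records)
  if (!nrow(rec)) stop("no displacement records", call. = FALSE)
  if (is.null(max_um)) {
    max_um <- ceiling(max(rec$displacement_um) / bin_width_um + 1e-9) *
      bin_width_um
    max_um <- max(max_um, bin_width_um)
  }
  nb <- ceiling(max_um / bin_width_um - 1e-9)
  edges_lo <- (seq_len(nb) - 1) * bin_width_um
  per_cell <- do.call(rbind, lapply(split(rec, rec$cell_id), function(d) {
    idx <- pmin(floor(d$displacement_um / bin_width_um) + 1L, nb)
    counts <- tabulate(idx, nbins = nb)
    data.frame(cell_id = d$cell_id[1], bin_lo = edges_lo,
               bin_hi = edges_lo + bin_width_um, count = counts,
               pct = 100 * counts / sum(counts))
  }))
  rownames(per_cell) <- NULL
  pct_mat <- matrix(per_cell$pct, nrow = nb)
  n_cells <- ncol(pct_mat)
  population <- data.frame(
    bin_lo = edges_lo, bin_hi = edges_lo + bin_width_um,
    mean_pct = rowMeans(pct_mat),
    sem_pct = if (n_cells > 1) apply(pct_mat, 1, stats::sd) / sqrt(n_cells)
              else rep(NA_real_, nb),
    n_cells = n_cells)
  list(per_cell = per_cell, population = population)
}

#' Stationary / intermediate / motile fractions per cell
#'
#' Classifies every 5-s window observation of a cell against the
#' displacement thresholds and reports the three fractions (they sum to 1
#' exactly), together with window and track counts — the published figure
#' "N" values can be read either way, so both are given.
#'
#' @param records A `displacement_records` data frame.
#' @param params An [analysis_parameters()].
#' @return A `motility_summary`: data frame with one row per cell
#'   (`cell_id`, `f_stationary`, `f_intermediate`, `f_motile`,
#'   `n_windows`, `n_tracks`) plus a pooled `"all_cells"` row stored in
#'   the `pooled` attribute. A cell with zero records is flagged via
#'   `n_windows = 0` rather than an error.
#' @export
classify_motility <- function(records, params = analysis_parameters()) {
  rec <- as.data.frame(records)
  if (!nrow(rec)) {
    out <- data.frame(cell_id = character(0), f_stationary = numeric(0),
                      f_intermediate = numeric(0), f_motile = numeric(0),
                      n_windows = integer(0), n_tracks = integer(0))
    class(out) <- c("motility_summary", "data.frame")
    return(out)
  }
  rec$class <- classify_displacement(rec$displacement_um, params)
  summarize <- function(d, id) {
    tab <- table(d$class)
    n <- nrow(d)
    data.frame(cell_id = id,
               f_stationary = as.numeric(tab[["stationary"]]) / n,
               f_intermediate = as.numeric(tab[["intermediate"]]) / n,
               f_motile = as.numeric(tab[["motile"]]) / n,
               n_windows = n,
               n_tracks = length(unique(d$track_id)))
  }
  out <- do.call(rbind, lapply(split(rec, rec$cell_id),
                               function(d) summarize(d, d$cell_id[1])))
  rownames(out) <- NULL
  pooled <- summarize(rec, "all_cells")
  structure(out, pooled = pooled,
            class = c("motility_summary", "data.frame"))
}

#' @export
print.motility_summary <- function(x, ...) {
  cat("Motility summary (fractions of 5-s windows per cell)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  p <- attr(x, "pooled")
  if (!is.null(p) && nrow(p)) {
    cat(sprintf("pooled: stationary %.3f, intermediate %.3f, motile %.3f (%d windows, %d tracks)\n",
                p$f_stationary, p$f_intermediate, p$f_motile,
                p$n_windows, p$n_tracks))
  }
  invisible(x)
}
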