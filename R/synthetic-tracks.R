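#' Simulate fiducial-mark tracks with known motility labels
#'
#' Generates trajectories of fiducial marks bound to the MT lattice:
#' *stationary* marks are a fixed point plus i.i.d. Gaussian localization
#' noise (per-coordinate sigma `stationary_sigma_um`), *motile* marks move
#' in a straight line at constant speed `motile_speed_um_s` in a random
#' fixed direction, with the same localization noise. The motile count is
#' assigned deterministically as `round(n_tracks * f_motile)` (not a
#' Bernoulli draw), so recovery tests have exact targets.
#'
#' @param n_tracks Number of tracks.
#' @param motion_mix List with `f_stationary` and `f_motile`, non-negative
#'   and summing to 1.
#' @param stationary_sigma_um Localization noise sigma (per coordinate).
#' @param motile_speed_um_s Speed of motile marks.
#' @param duration_s Track duration (>= 5 s).
#' @param dt_s Sampling interval (> 0).
#' @param seed Integer seed.
#' @param field_um Side of the square field tracks start in.
#' @param cell_id Label attached to all tracks.
#' @return List with `tracks` (a `track_set` data frame: `track_id`,
#'   `t_s`, `x_um`, `y_um`, `cell_id`) and `truth` (data frame `track_id`,
#'   `label` in {stationary, motile}).
#' @export
#' @examples
#' s <- simulate_tracks(10, list(f_stationary = 0.5, f_motile = 0.5),
#'                      seed = 1)
#' table(s$truth$label)
simulate_tracks <- function(n_tracks,
                            motion_mix = list(f_stationary = 0.5,
                                              f_motile = 0.5),
                            stationary_sigma_um = 0.02,
                            motile_speed_um_s = 0.1,
                            duration_s = 120,
                            dt_s = 1,
                            seed = 1,
                            field_um = 30,
                            cell_id = "cell1") {
  fs <- motion_mix$f_stationary; fm <- motion_mix$f_motile
  if (is.null(fs) || is.null(fm) || fs < 0 || fm < 0 ||
      abs(fs + fm - 1) > 1e-9) {
    stop("motion fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (dt_s <= 0) stop("`dt_s` must be positive", call. = FALSE)
  if (duration_s < 5) stop("`duration_s` must be at least 5 s",
                           call. = FALSE)
  if (stationary_sigma_um < 0 || motile_speed_um_s < 0) {
    stop("noise and speed must be non-negative", call. = FALSE)
  }
  n_motile <- round(n_tracks * fm)
  labels <- rep(c("stationary", "motile"),
                c(n_tracks - n_motile, n_motile))
  t <- seq(0, duration_s, by = dt_s)

  with_seed(seed, {
    rows <- lapply(seq_len(n_tracks), function(k) {
      x0 <- stats::runif(1, 0, field_um)
      y0 <- stats::runif(1, 0, field_um)
      if (labels[k] == "motile") {
        th <- stats::runif(1, 0, 2 * pi)
        x <- x0 + motile_speed_um_s * t * cos(th)
        y <- y0 + motile_speed_um_s * t * sin(th)
      } else {
        x <- rep(x0, length(t)); y <- rep(y0, length(t))
      }
      if (stationary_sigma_um > 0) {
        x <- x + stats::rnorm(length(t), 0, stationary_sigma_um)
        y <- y + stats::rnorm(length(t), 0, stationary_sigma_um)
      }
      data.frame(track_id = k, t_s = t, x_um = x, y_um = y,
                 cell_id = cell_id)
    })
    tracks <- do.call(rbind, rows)
    class(tracks) <- c("track_set", "data.frame")
    list(tracks = tracks,
         truth = data.frame(track_id = seq_len(n_tracks), label = labels))
  })
}

#' Simulate a field of view with marker-positive and -negative cells
#'
#' Emulates a depletion experiment read out by fluorescence: cells
#' negative for the marker (e.g. an shRNA reporter) have mean intensity
#' around a reference level, positive cells around `fold` times it, with
#' multiplicative Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param n_positive,n_negative Cell counts; at least one negative cell is
#'   required (it defines the normalizer).
#' @param fold True intensity ratio positive / negative (> 0).
#' @param noise_cv Coefficient of variation of per-cell intensities.
#' @param seed Integer seed.
#' @param mean_negative Reference mean intensity of negative cells.
#' @return A `field_of_view` data frame: `cell_id`, `positive` (logical),
#'   `mean_intensity`; attribute `true_fold`.
#' @export
generate_fov_intensity <- function(n_positive, n_negative, fold,
                                   noise_cv = 0, seed = 1,
                                   mean_negative = 100) {
  if (n_negative < 1) {
    stop("at least one marker-negative cell is required", call. = FALSE)
  }
  if (fold <= 0) stop("`fold` must be positive", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be non-negative", call. = FALSE)
  n <- n_positive + n_negative
  positive <- rep(c(FALSE, TRUE), c(n_negative, n_positive))
  mu <- ifelse(positive, fold * mean_negative, mean_negative)
  vals <- with_seed(seed, {
    v <- mu * (1 + stats::rnorm(n, 0, noise_cv))
    pmax(v, 1e-6 * mean_negative)
  })
  structure(data.frame(cell_id = seq_len(n), positive = positive,
                       mean_intensity = vals),
            true_fold = fold,
            class = c("field_of_view", "data.frame"))
}

#' Write / read a track table as CSV
#'
#' The on-disk schema is `track_id,t_s,x_um,y_um[,cell_id,...]` with units
#' fixed by the column names (seconds, micrometers).
#'
#' @param tracks A `track_set` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}
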