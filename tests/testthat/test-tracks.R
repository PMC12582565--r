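toy_tracks <- function() {
  data.frame(track_id = rep(1:2, each = 3),
             t_s = rep(c(0, 1, 2), 2),
             x_um = c(0, 0.1, 0.2, 5, 5, 5),
             y_um = c(0, 0, 0, 1, 1, 1))
}

test_that("track CSV round-trips, sorts, converts units, and validates", {
  f <- withr::local_tempfile(fileext = ".csv")
  tr <- toy_tracks()
  write_tracks_csv(tr, f)
  back <- read_tracks_csv(f)
  expect_equal(as.data.frame(back), tr, ignore_attr = TRUE)

  # shuffled rows come back identical after sorting
  shuf <- tr[sample(nrow(tr)), ]
  write_tracks_csv(shuf, f)
  expect_equal(as.data.frame(read_tracks_csv(f)), tr, ignore_attr = TRUE)

  # nm positions are divided by 1000
  nm <- tr
  nm$x_um <- nm$x_um * 1000
  nm$y_um <- nm$y_um * 1000
  write_tracks_csv(nm, f)
  back_nm <- read_tracks_csv(f, units = list(position = "nm", time = "s"))
  expect_equal(back_nm$x_um, tr$x_um)

  # schema errors name the missing columns
  bad <- tr
  names(bad)[3] <- "pos_x"
  write_tracks_csv(bad, f)
  expect_error(read_tracks_csv(f), "x_um")
  # duplicate (id, t) is rejected
  dup <- rbind(tr, tr[1, ])
  write_tracks_csv(dup, f)
  expect_error(read_tracks_csv(f), "duplicate")
})

test_that("time normalization keeps grids, subsamples, and respects gaps", {
  tr <- toy_tracks()
  expect_equal(as.data.frame(normalize_tracks(tr, 1)), tr,
               ignore_attr = TRUE)

  # 0.1 s sampling resampled to 1 s keeps every 10th sample
  fast <- data.frame(track_id = 1, t_s = seq(0, 12, by = 0.1))
  fast$x_um <- fast$t_s * 0.1
  fast$y_um <- 0
  slow <- normalize_tracks(fast, 1)
  expect_equal(slow$t_s, 0:12)
  expect_equal(slow$x_um, (0:12) * 0.1, tolerance = 1e-9)

  # a 3 s dropout leaves grid points absent, later samples retained
  gap <- data.frame(track_id = 1, t_s = c(0, 1, 2, 6, 7, 8),
                    x_um = 0, y_um = 0)
  out <- normalize_tracks(gap, 1)
  expect_equal(out$t_s, c(0, 1, 2, 6, 7, 8))

  # tracks reduced below 2 samples are dropped and logged
  lone <- data.frame(track_id = c(1, 1, 2, 2), t_s = c(0, 1, 0, 0.2),
                     x_um = 0, y_um = 0)
  out2 <- normalize_tracks(lone, 1)
  expect_equal(unique(out2$track_id), 1)
  expect_equal(attr(out2, "dropped"), "2")
})

test_that("5-s windows count, measure, and classify as published", {
  # static noiseless 120 s track at 1 s sampling: 24 windows, all zero
  s <- simulate_tracks(1, list(f_stationary = 1, f_motile = 0),
                       stationary_sigma_um = 0, seed = 1)
  rec <- five_second_displacements(s$tracks)
  expect_equal(nrow(rec), 24)
  expect_true(all(rec$displacement_um == 0))
  expect_true(all(rec$class == "stationary"))

  # straight motion at 0.1 um/s: every 5-s displacement exactly 0.5 um
  s2 <- simulate_tracks(1, list(f_stationary = 0, f_motile = 1),
                        stationary_sigma_um = 0, motile_speed_um_s = 0.1,
                        seed = 2)
  rec2 <- five_second_displacements(s2$tracks)
  expect_equal(rec2$displacement_um, rep(0.5, 24), tolerance = 1e-9)
  expect_true(all(rec2$class == "motile"))

  # displacements exactly at a threshold are intermediate (strict bounds)
  tr <- data.frame(track_id = 1, t_s = 0:5,
                   x_um = c(0, 0, 0, 0, 0, 0.15), y_um = 0)
  rec3 <- five_second_displacements(tr)
  expect_equal(rec3$displacement_um, 0.15)
  expect_equal(as.character(rec3$class), "intermediate")
  tr$x_um[6] <- 0.3
  expect_equal(as.character(five_second_displacements(tr)$class),
               "intermediate")
  tr$x_um[6] <- 0.301
  expect_equal(as.character(five_second_displacements(tr)$class),
               "motile")
})

test_that("gap-free duration D at 1 s yields floor(D/5) windows", {
  for (D in c(17, 30, 59, 120)) {
    tr <- data.frame(track_id = 1, t_s = 0:D, x_um = 0, y_um = 0)
    expect_equal(nrow(five_second_displacements(tr)), floor(D / 5))
  }
})

test_that("displacement binning matches hand counts and percentages", {
  rec <- data.frame(track_id = 1:2, cell_id = "c1",
                    window_start_s = 0,
                    displacement_um = c(0.02, 0.07))
  b <- bin_displacements(rec)
  expect_equal(b$per_cell$pct[1:2], c(50, 50))
  expect_equal(sum(b$per_cell$pct), 100, tolerance = 1e-6)

  rec0 <- data.frame(track_id = 1:3, cell_id = "c1",
                     window_start_s = 0, displacement_um = 0)
  b0 <- bin_displacements(rec0)
  expect_equal(b0$per_cell$pct[1], 100)
})

test_that("binned Rayleigh displacements match the closed-form law", {
  s <- simulate_tracks(420, list(f_stationary = 1, f_motile = 0),
                       stationary_sigma_um = 0.02, seed = 33)
  rec <- five_second_displacements(s$tracks)
  expect_gt(nrow(rec), 1e4 - 100)
  b <- bin_displacements(rec)
  counts <- b$per_cell$count
  obs <- counts / sum(counts)
  edges <- c(b$per_cell$bin_lo, max(b$per_cell$bin_hi))
  scale <- 0.02 * sqrt(2)  # difference of two N(0, sigma^2) per axis
  expected <- diff(rayleigh_cdf(edges, scale))
  expected[length(expected)] <- expected[length(expected)] +
    1 - rayleigh_cdf(edges[length(edges)], scale)
  expect_lt(max(abs(obs - expected)), 0.01)
})

test_that("motility fractions are exact counts and sum to one", {
  rec <- data.frame(track_id = 1:4, cell_id = "c1", window_start_s = 0,
                    displacement_um = c(0.1, 0.1, 0.5, 0.2))
  ms <- classify_motility(rec)
  expect_equal(ms$f_stationary, 0.5)
  expect_equal(ms$f_motile, 0.25)
  expect_equal(ms$f_intermediate, 0.25)
  expect_equal(ms$f_stationary + ms$f_intermediate + ms$f_motile, 1)
  expect_equal(ms$n_windows, 4)
  expect_equal(ms$n_tracks, 4)
  empty <- classify_motility(rec[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("simulated pure populations classify correctly", {
  st <- simulate_tracks(300, list(f_stationary = 1, f_motile = 0),
                        seed = 3)
  ps <- attr(classify_motility(five_second_displacements(st$tracks)),
             "pooled")
  expect_gte(ps$f_stationary, 0.99)
  mo <- simulate_tracks(300, list(f_stationary = 0, f_motile = 1),
                        seed = 4)
  pm <- attr(classify_motility(five_second_displacements(mo$tracks)),
             "pooled")
  expect_gte(pm$f_motile, 0.99)
})

test_that("track simulator validates the motion mix", {
  expect_error(simulate_tracks(10, list(f_stationary = 0.6,
                                        f_motile = 0.6)), "sum to 1")
  expect_error(simulate_tracks(10, list(f_stationary = -0.5,
                                        f_motile = 1.5)), "non-negative")
  expect_error(simulate_tracks(10, list(f_stationary = 1, f_motile = 0),
                               duration_s = 3), "at least 5")
})
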