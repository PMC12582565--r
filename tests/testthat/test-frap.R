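test_that("belt and bleached zones partition the cell exactly", {
  m <- generate_cell_mask("ellipse", c(12, 8), seed = 4)
  rois <- define_frap_rois(m, axis = "x", belt_width_um = 5)
  expect_gt(sum(rois$bleach[[1]]), 0)
  expect_gt(sum(rois$bleach[[2]]), 0)
  total <- rois$belt + rois$bleach[[1]] + rois$bleach[[2]]
  expect_true(all(total[m$mask] == 1))
  expect_true(all(total[!m$mask] == 0))
  # 5 um at 0.1 um/px -> 50 px wide stripe
  cols_in_belt <- unique(which(rois$belt, arr.ind = TRUE)[, 1])
  expect_equal(length(cols_in_belt), 50)
  expect_error(define_frap_rois(m, belt_width_um = 100), "whole cell")
})

test_that("zero-translocation ground truth is zero at every frame", {
  m <- generate_cell_mask("ellipse", c(12, 8), seed = 4)
  sim <- simulate_frap_series(m, sliding = list(n_translocating = 0,
                                                speed_um_s = 0.02),
                              n_frames = 11, seed = 5)
  expect_true(all(sim$truth$area_by_frame_um2 == 0))
  sm <- displaced_mt_area(sim$series, sim$rois)
  expect_lt(sm$readout_area_um2, 0.05 * sm$belt_area_um2)
})

test_that("ground-truth area matches an independent analytic raster count", {
  m <- generate_cell_mask("ellipse", c(13, 8), seed = 6)
  sim <- simulate_frap_series(m, sliding = list(n_translocating = 1,
                                                speed_um_s = 0.03),
                              n_frames = 16, seed = 7)
  px <- m$calibration$pixel_size_um
  rois <- sim$rois
  zones <- rois$bleach[[1]] | rois$bleach[[2]]
  # analytic filament position at frame k: centered at belt center shifted
  # by v*t along x, length 4, thickness 0.5; count pixel centers within
  # thickness/2 of the segment (the renderer's coverage >= 0.5 rule)
  X <- (row(m$mask) - 0.5) * px
  Y <- (col(m$mask) - 0.5) * px
  for (k in c(8, 12, 16)) {
    shift <- 0.03 * sim$truth$t_s[k]
    c_along <- rois$center_um + shift
    # recover the filament's cross position from the bright zone pixels
    w <- which(sim$series$pixels[, , k] > 50 & zones, arr.ind = TRUE)
    fil_y <- stats::median((w[, 2] - 0.5) * px)
    # distance from pixel centers to the analytic segment (length 4 um,
    # thickness 0.5 um = 5 px; renderer covers pixels within 2.5 px)
    dx <- pmax(pmax((c_along - 2) - X, X - (c_along + 2)), 0)
    dist_px <- sqrt(dx^2 + (Y - fil_y)^2) / px
    covered <- dist_px <= 2.5 & m$mask
    analytic <- sum(covered & zones) * px^2
    expect_gt(analytic, 0)
    expect_equal(sim$truth$area_by_frame_um2[k], analytic,
                 tolerance = 0.15)
  }
})

test_that("a filament fully inside a bleached zone is recovered within 20%", {
  m <- generate_cell_mask("ellipse", c(13, 8), seed = 6)
  sim <- simulate_frap_series(m, sliding = list(n_translocating = 1,
                                                speed_um_s = 0.02),
                              n_frames = 31, seed = 8)
  sm <- displaced_mt_area(sim$series, sim$rois)
  truth <- sim$truth$area_by_frame_um2[sm$readout_frame + 1]
  expect_gt(truth, 0)
  expect_lt(abs(sm$readout_area_um2 - truth) / truth, 0.20)
})

test_that("readout lands on the frame nearest 300 s and flags truncation", {
  m <- generate_cell_mask("ellipse", c(12, 8), seed = 4)
  sim <- simulate_frap_series(m, sliding = list(n_translocating = 2,
                                                speed_um_s = 0.02),
                              n_frames = 31, seed = 9)
  sm <- displaced_mt_area(sim$series, sim$rois, readout_time_s = 300)
  expect_equal(sm$readout_frame, 30)  # 10 s frames: frame 30 = 300 s
  expect_false(sm$truncated)
  expect_equal(sm$per_frame$area_um2[1], 0)  # residual-subtracted frame 0
  short <- image_stack(sim$series$pixels[, , 1:5],
                       sim$series$calibration, dim3 = "t")
  sm2 <- displaced_mt_area(short, sim$rois, readout_time_s = 300)
  expect_true(sm2$truncated)
  expect_equal(sm2$readout_frame, 4)
})

test_that("the readout is robust to a 10% threshold change", {
  m <- generate_cell_mask("ellipse", c(13, 8), seed = 6)
  sim <- simulate_frap_series(m, sliding = list(n_translocating = 3,
                                                speed_um_s = 0.02),
                              n_frames = 31, seed = 10)
  base <- displaced_mt_area(sim$series, sim$rois)
  up <- displaced_mt_area(sim$series, sim$rois, threshold_mode = "fixed",
                          threshold_value = base$threshold * 1.1)
  dn <- displaced_mt_area(sim$series, sim$rois, threshold_mode = "fixed",
                          threshold_value = base$threshold * 0.9)
  expect_lt(abs(up$readout_area_um2 - base$readout_area_um2) /
              base$readout_area_um2, 0.15)
  expect_lt(abs(dn$readout_area_um2 - base$readout_area_um2) /
              base$readout_area_um2, 0.15)
})
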