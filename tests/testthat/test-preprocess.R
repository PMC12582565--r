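cal <- pixel_calibration(0.1)

test_that("Richardson-Lucy sharpens a blurred point and conserves flux", {
  img <- matrix(0, 80, 80)
  img[40, 40] <- 1000
  blurred <- image_stack(pmax(as.matrix(EBImage::gblur(img, 1.5)), 0), cal)
  out <- richardson_lucy_deconvolve(blurred, psf_sigma_um = 0.15,
                                    iterations = 30)
  expect_gt(max(out$pixels), max(blurred$pixels))
  expect_true(all(out$pixels >= 0))
  expect_lt(abs(sum(out$pixels) - sum(blurred$pixels)) / sum(blurred$pixels),
            0.01)
  expect_error(richardson_lucy_deconvolve(blurred, 0.15, iterations = 0),
               "positive integer")
  bad <- blurred
  bad$pixels[1, 1] <- NA
  expect_error(richardson_lucy_deconvolve(unclass(bad)$pixels, 0.15,
                                          calibration = cal), "finite")
})

test_that("RL separates two parallel lines 0.4 um apart blurred at 0.15 um", {
  img <- matrix(0, 100, 100)
  img[, 48] <- 100  # two vertical lines 4 px = 0.4 um apart
  img[, 52] <- 100
  blurred <- image_stack(pmax(as.matrix(EBImage::gblur(img, 1.5)), 0), cal)
  profile_b <- blurred$pixels[50, 40:60]
  out <- richardson_lucy_deconvolve(blurred, 0.15, iterations = 40)
  profile <- out$pixels[50, 40:60]
  n_max <- function(p) {
    sum(diff(sign(diff(p))) == -2)
  }
  expect_equal(n_max(profile), 2)  # both lines resolved after deconvolution
  # and the separation is sharper: the valley between the peaks deepens
  contrast <- function(p) 1 - p[11] / max(p)  # midpoint between the lines
  expect_gt(contrast(profile), contrast(profile_b))
})

test_that("max projection selects the stated ventral slices", {
  arr <- array(0, c(10, 10, 7))
  for (k in 1:7) arr[, , k] <- k
  st <- image_stack(arr, pixel_calibration(0.1, z_step_um = 0.4),
                    dim3 = "z")
  # ventral 1.2 um at 0.4 um step: slices at depth 0, 0.4, 0.8 -> max = 3
  mip <- max_intensity_projection(st, 1.2)
  expect_true(all(mip$pixels == 3))
  # per-pixel max over chosen slices
  arr2 <- array(0, c(2, 2, 3))
  arr2[1, 1, ] <- c(1, 0, 5)
  st2 <- image_stack(arr2, pixel_calibration(0.1, z_step_um = 0.4),
                     dim3 = "z")
  expect_equal(max_intensity_projection(st2)$pixels[1, 1], 5)
  # single-slice identity
  arr1 <- array(runif(25), c(5, 5, 1))
  st1 <- image_stack(arr1, pixel_calibration(0.1, z_step_um = 0.4),
                     dim3 = "z")
  expect_equal(max_intensity_projection(st1)$pixels, arr1[, , 1])
  expect_error(max_intensity_projection(st, c(5, 6)), "no slices")
})

test_that("isodata converges to the intermeans threshold", {
  img <- matrix(10, 40, 40)
  img[, 21:40] <- 100
  mask <- matrix(TRUE, 40, 40)
  res <- isodata_threshold(img, mask)
  expect_equal(res$threshold, 55, tolerance = 1e-6)
  expect_equal(sum(res$mask), sum(img == 100))
  expect_error(isodata_threshold(matrix(0, 10, 10), matrix(TRUE, 10, 10)),
               "constant")
})

test_that("isodata recalls at least 90% of true filament pixels", {
  sc <- small_parallel_scene()
  res <- isodata_threshold(sc$render$image, sc$mask)
  truth <- sc$render$truth$filament_mask
  expect_gt(sum(res$mask & truth) / sum(truth), 0.90)
  expect_true(all(!res$mask[!sc$mask$mask]))  # subset of cell mask
})

test_that("perfect threshold is optimized for a bright periphery", {
  m <- generate_cell_mask("ellipse", c(8, 8), seed = 2)
  g <- compute_border_geometry(m)
  img <- matrix(0, nrow(m$mask), ncol(m$mask))
  img[m$mask] <- 20                      # dim interior
  img[!is.na(g$distance_um) & g$distance_um <= 1.5] <- 100  # bright rim
  img <- img + matrix(rnorm(length(img), 0, 1), nrow(img))
  img[img < 0] <- 0
  perfect <- per_cell_perfect_threshold(img, m, band_width_um = 1,
                                        calibration = m$calibration)
  global <- isodata_threshold(img, m)
  expect_gt(perfect$threshold, global$threshold)

  # band wider than the cell radius: identical to global isodata
  wide <- per_cell_perfect_threshold(img, m, band_width_um = 50,
                                     calibration = m$calibration)
  expect_equal(wide$threshold, global$threshold)

  flat <- matrix(5, nrow(m$mask), ncol(m$mask))
  expect_error(per_cell_perfect_threshold(flat, m, 1,
                                          calibration = m$calibration),
               "constant")
})

test_that("peripheral band matches annulus area, monotonicity and the brute-force distance oracle", {
  disk <- generate_cell_mask("ellipse", c(10, 10), seed = 3)
  band2 <- peripheral_band(disk, 2)
  area <- sum(band2) * 0.01
  expect_lt(abs(area - pi * (10^2 - 8^2)) / (pi * (10^2 - 8^2)), 0.02)
  band1 <- peripheral_band(disk, 1)
  expect_true(all(band2[band1]))  # band(1) subset of band(2)
  expect_error(peripheral_band(disk, -1), "positive")

  # irregular mask vs exhaustive nearest-border distance
  irr <- generate_cell_mask("smoothed_polygon", c(4, 3), seed = 8,
                            frame_um = 11)
  bandw <- peripheral_band(irr, 1.2)
  od <- oracle_distance_um(irr$mask, irr$calibration$pixel_size_um)
  expect_equal(sum(bandw), sum(od <= 1.2, na.rm = TRUE))
})
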