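cal <- pixel_calibration(0.1)

test_that("histogram bins, edges, and normalization behave as specified", {
  geom <- compute_border_geometry(
    generate_cell_mask("ellipse", c(6, 6), seed = 1))
  a <- matrix(NA_real_, nrow(geom$mask), ncol(geom$mask))
  sel <- which(!is.na(geom$distance_um) & geom$distance_um < 1)
  # all parallel
  a[sel] <- 0
  h <- bin_directionality(a, geom)
  expect_equal(h$fraction[1], 1)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
  # edge cases: 90 goes to the last bin, interior edges to the upper bin
  a[sel] <- 90
  expect_equal(bin_directionality(a, geom)$fraction[9], 1)
  a[sel] <- 10
  expect_equal(bin_directionality(a, geom)$fraction[2], 1)
  # empty band is flagged, not an error
  a[] <- NA
  h0 <- bin_directionality(a, geom)
  expect_true(attr(h0, "empty"))
  expect_equal(attr(h0, "n_pixels"), 0)
  expect_true(all(is.na(h0$fraction)))
})

test_that("distance-resolved histograms partition the valid pixels", {
  sc <- small_parallel_scene()
  da <- directionality_analysis(sc$render$image, sc$mask,
                                deconvolve = FALSE)
  bands <- directionality_vs_distance(da$angles, da$geometry,
                                      band_edges_um = 0:5)
  # single band [0,1) is identical to bin_directionality
  expect_equal(bands[[1]]$count, da$histogram$count)
  n_by_band <- vapply(bands, function(h) attr(h, "n_pixels"), integer(1))
  a <- unclass(da$angles)
  d <- da$geometry$distance_um
  total <- sum(!is.na(a) & !is.na(d) & d < 5)
  expect_equal(sum(n_by_band), total)
  expect_error(directionality_vs_distance(da$angles, da$geometry,
                                          band_edges_um = c(0, 2, 1)),
               "increasing")
})

test_that("a parallel rim over an isotropic interior is detected as such", {
  m <- generate_cell_mask("ellipse", c(11, 9), seed = 51)
  rim <- render_mt_image(m, filament_spec(n_filaments = 45,
                                          seed_band_um = c(0, 1.5),
                                          length_um = 4),
                         seed = 52)
  iso <- render_mt_image(m, filament_spec(n_filaments = 45,
                                          orientation_model = "isotropic",
                                          seed_band_um = c(2.5, 50),
                                          length_um = 4),
                         seed = 53)
  img <- image_stack(pmax(rim$image$pixels, iso$image$pixels), m$calibration)
  da <- directionality_analysis(img, m, deconvolve = FALSE)
  bands <- directionality_vs_distance(da$angles, da$geometry)
  expect_gt(bands[["[0,1)"]]$fraction[1], bands[["[2,3)"]]$fraction[1])
})

test_that("perfect and population-standard thresholds give similar histograms", {
  # the two thresholding conditions should provide similar outputs
  sc <- small_parallel_scene(seed_mask = 61, seed_render = 62)
  img <- richardson_lucy_deconvolve(sc$render$image, 0.15, 20)
  geom <- compute_border_geometry(sc$mask)
  hist_for <- function(thr) {
    f <- compute_orientation_field(img, thr, cell_mask = sc$mask)
    bin_directionality(angle_to_border(f, geom), geom)
  }
  h_perfect <- hist_for(per_cell_perfect_threshold(img, sc$mask, 1))
  h_standard <- hist_for(isodata_threshold(img, sc$mask))
  expect_lt(max(abs(h_perfect$fraction - h_standard$fraction)), 0.05)
})

test_that("pooling supports pixel and equal-cell weighting", {
  sc <- small_parallel_scene(seed_mask = 71, seed_render = 72)
  da <- directionality_analysis(sc$render$image, sc$mask,
                                deconvolve = FALSE, cell_id = "c1")
  h <- da$histogram
  pooled_px <- pool_directionality(list(h, h), weights = "pixel")
  pooled_cell <- pool_directionality(list(h, h), weights = "cell")
  expect_equal(pooled_px$fraction, h$fraction)
  expect_equal(pooled_cell$fraction, h$fraction)
  expect_equal(attr(pooled_px, "n_pixels"), 2L * attr(h, "n_pixels"))
})
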