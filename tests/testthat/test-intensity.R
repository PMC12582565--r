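test_that("peripheral mean intensity reads the outer band", {
  m <- generate_cell_mask("ellipse", c(8, 8), seed = 2)
  flat <- matrix(7, nrow(m$mask), ncol(m$mask))
  expect_equal(peripheral_mean_intensity(flat, m), 7)

  # bright ring exactly filling the 2 um band over dark interior
  band <- peripheral_band(m, 2)
  ring <- matrix(0, nrow(m$mask), ncol(m$mask))
  ring[band] <- 100
  expect_equal(peripheral_mean_intensity(ring, m, width_um = 2), 100)
  expect_lt(mean(ring[m$mask]), 100)

  # erasing the band's filaments lowers the band mean
  sc <- small_parallel_scene(seed_mask = 81, seed_render = 82)
  erased <- sc$render$image$pixels
  erased[peripheral_band(sc$mask, 2)] <- 0
  expect_lt(peripheral_mean_intensity(erased, sc$mask),
            peripheral_mean_intensity(sc$render$image$pixels, sc$mask,
                                      calibration = sc$mask$calibration))

  # width growing to the cell radius converges to the whole-cell mean
  big <- peripheral_mean_intensity(sc$render$image, sc$mask,
                                   width_um = 50)
  expect_equal(big, mean(sc$render$image$pixels[sc$mask$mask]))
})

test_that("depletion fold is the exact ratio to the negative mean", {
  fov <- generate_fov_intensity(5, 5, fold = 0.5, noise_cv = 0, seed = 1)
  df <- depletion_fold(fov)
  expect_equal(df$fold, rep(0.5, 5))

  # scale invariance is exact
  fov2 <- fov
  fov2$mean_intensity <- fov2$mean_intensity * 3.7
  expect_equal(depletion_fold(fov2)$fold, df$fold)

  # a negative cell normalized to its own group averages to 1
  neg <- fov[!fov$positive, ]
  self <- neg$mean_intensity / mean(neg$mean_intensity)
  expect_equal(mean(self), 1)

  expect_error(depletion_fold(fov[fov$positive, ]), "negative")
  expect_error(generate_fov_intensity(5, 0, fold = 0.5), "negative")
  expect_error(generate_fov_intensity(5, 5, fold = 0), "positive")
})

test_that("noisy depletion folds recover the simulated ratio", {
  fov <- generate_fov_intensity(50, 50, fold = 0.3, noise_cv = 0.1,
                                seed = 7)
  df <- depletion_fold(fov)
  sem <- stats::sd(df$fold) / sqrt(nrow(df))
  expect_lt(abs(mean(df$fold) - 0.3), 3 * sem + 0.3 * 0.1 / sqrt(50))
  # identical intensities when noise is off and fold is 1
  flat <- generate_fov_intensity(4, 4, fold = 1, noise_cv = 0, seed = 1)
  expect_true(all(flat$mean_intensity == flat$mean_intensity[1]))
})

make_hist <- function(fracs, n = 1000) {
  counts <- round(fracs * n)
  structure(data.frame(bin_lo = seq(0, 80, 10), bin_hi = seq(10, 90, 10),
                       count = counts, fraction = fracs),
            band = c(0, 1), n_pixels = sum(counts), cell_id = NA,
            empty = FALSE,
            class = c("directionality_histogram", "data.frame"))
}

test_that("identical groups give null statistics", {
  h1 <- make_hist(c(0.5, 0.2, 0.1, 0.05, 0.05, 0.04, 0.03, 0.02, 0.01))
  h2 <- make_hist(c(0.45, 0.25, 0.1, 0.05, 0.05, 0.04, 0.03, 0.02, 0.01))
  ang <- runif(500, 0, 90)
  cmp <- suppressWarnings(
    compare_directionality(list(h1, h2), list(h1, h2),
                           angles_a = ang, angles_b = ang))
  expect_true(all(cmp$per_bin$t_stat == 0))
  expect_true(all(cmp$per_bin$p == 1))
  expect_equal(cmp$ks$statistic, 0)
  expect_equal(cmp$effect_bin0, 0)
})

test_that("comparison is symmetric up to the sign of the effect", {
  h1 <- make_hist(c(0.5, 0.2, 0.1, 0.05, 0.05, 0.04, 0.03, 0.02, 0.01))
  h2 <- make_hist(c(0.45, 0.25, 0.1, 0.05, 0.05, 0.04, 0.03, 0.02, 0.01))
  h3 <- make_hist(rep(1 / 9, 9))
  h4 <- make_hist(c(0.15, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.15))
  ab <- suppressWarnings(compare_directionality(list(h1, h2), list(h3, h4)))
  ba <- suppressWarnings(compare_directionality(list(h3, h4), list(h1, h2)))
  expect_equal(ab$per_bin$p, ba$per_bin$p)
  expect_equal(ab$effect_bin0, -ba$effect_bin0)
})

test_that("single-cell groups refuse t-tests but keep the K-S test", {
  h1 <- make_hist(c(0.5, 0.2, 0.1, 0.05, 0.05, 0.04, 0.03, 0.02, 0.01))
  h3 <- make_hist(rep(1 / 9, 9))
  cmp <- compare_directionality(list(h1), list(h3),
                                angles_a = runif(200, 0, 20),
                                angles_b = runif(200, 0, 90))
  expect_null(cmp$per_bin)
  expect_match(cmp$t_test_error, "two cells")
  expect_gt(cmp$ks$statistic, 0)
})
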