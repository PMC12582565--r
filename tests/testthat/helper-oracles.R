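# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's own fast paths:
# distances are exhaustive searches, tangents are contour fits, histograms
# are closed-form laws.

# Contour-fit border tangent: nearest boundary pixel by exhaustive search,
# then a total-least-squares line through all boundary pixels within
# fit_radius_um of it.
oracle_tangent_deg <- function(mask_mat, pixel_size_um, query_idx,
                               fit_radius_um = 0.5) {
  bp <- perimt:::boundary_pixels(mask_mat)
  bx <- (bp[, 1] - 0.5) * pixel_size_um
  by <- (bp[, 2] - 0.5) * pixel_size_um
  qx <- (query_idx[, 1] - 0.5) * pixel_size_um
  qy <- (query_idx[, 2] - 0.5) * pixel_size_um
  vapply(seq_len(nrow(query_idx)), function(k) {
    d2 <- (bx - qx[k])^2 + (by - qy[k])^2
    nb <- which.min(d2)
    near <- (bx - bx[nb])^2 + (by - by[nb])^2 <= fit_radius_um^2
    X <- cbind(bx[near] - mean(bx[near]), by[near] - mean(by[near]))
    v <- svd(X, nu = 0, nv = 2)$v[, 1]
    (atan2(v[2], v[1]) * 180 / pi) %% 180
  }, numeric(1))
}

# Exhaustive nearest-background distance (um) for every in-mask pixel,
# using the same pixel-center-to-sub-pixel-border convention as the
# package (half a pixel short of the nearest background pixel center).
oracle_distance_um <- function(mask_mat, pixel_size_um) {
  bg <- which(!mask_mat, arr.ind = TRUE)
  fg <- which(mask_mat, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask_mat), ncol(mask_mat))
  for (k in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2
    d <- (sqrt(min(d2)) - 0.5) * pixel_size_um
    out[fg[k, 1], fg[k, 2]] <- max(d, 0)
  }
  out
}

# Acute angular difference between two orientations (degrees).
ang_err <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

rayleigh_cdf <- function(x, scale) 1 - exp(-x^2 / (2 * scale^2))

# A horizontal full-width stripe mask: both borders are exactly straight,
# the tangent field is exactly 0 degrees.
stripe_mask <- function(nx = 200, ny = 200, j_lo = 60, j_hi = 140,
                        pixel_size_um = 0.1) {
  m <- matrix(FALSE, nx, ny)
  m[, j_lo:j_hi] <- TRUE
  as_cell_mask(m, pixel_calibration(pixel_size_um))
}

# Small standard cell + parallel render reused by several files.
small_parallel_scene <- function(seed_mask = 11, seed_render = 12,
                                 n_filaments = 40) {
  m <- generate_cell_mask("ellipse", c(10, 7), seed = seed_mask)
  r <- render_mt_image(m, filament_spec(n_filaments = n_filaments),
                       seed = seed_render)
  list(mask = m, render = r)
}
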