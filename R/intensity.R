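#' Mean intensity within the peripheral band of a cell
#'
#' Mean pixel intensity over the outer `width_um` of the cell (default
#' 2 um), the standard readout for peripheral MT abundance.
#'
#' @param image An [image_stack()] or matrix.
#' @param mask A `cell_mask` or binary matrix.
#' @param width_um Band width in micrometers.
#' @param calibration Required when neither argument carries one.
#' @return Mean intensity (scalar, arbitrary units).
#' @export
peripheral_mean_intensity <- function(image, mask, width_um = 2,
                                      calibration = NULL) {
  calibration <- tryCatch(get_calibration(image, calibration),
                          error = function(e) get_calibration(mask))
  d <- as_pixels(image)
  band <- peripheral_band(mask, width_um, calibration)
  if (!any(band)) stop("peripheral band is empty", call. = FALSE)
  mean(d[band])
}

#' Depletion fold of marker-positive cells
#'
#' Normalizes the mean intensity of every marker-positive cell to the
#' average intensity of the marker-negative cells in the same field of
#' view: `fold = intensity(positive cell) / mean(intensity of negative
#' cells)`. The readout is scale-invariant: multiplying all intensities in
#' the field by a constant leaves every fold unchanged.
#'
#' @param fov A `field_of_view` data frame (columns `cell_id`, `positive`,
#'   `mean_intensity`), e.g. from [generate_fov_intensity()].
#' @return Data frame `cell_id`, `fold` for the positive cells; attributes
#'   `negative_mean` and `mean_fold`.
#' @export
depletion_fold <- function(fov) {
  f <- as.data.frame(fov)
  need <- c("cell_id", "positive", "mean_intensity")
  if (!all(need %in% names(f))) {
    stop("fov needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  neg <- f$mean_intensity[!f$positive]
  if (!length(neg)) {
    stop("no marker-negative cells: normalizer undefined", call. = FALSE)
  }
  ref <- mean(neg)
  if (ref <= 0) stop("negative-cell mean intensity is not positive",
                     call. = FALSE)
  pos <- f[f$positive, , drop = FALSE]
  out <- data.frame(cell_id = pos$cell_id,
                    fold = pos$mean_intensity / ref)
  structure(out, negative_mean = ref, mean_fold = mean(out$fold))
}

#' Compare directionality between two groups of cells
#'
#' The two statistical tests reported with directionality histograms: an
#' unpaired (Welch) two-sample t-test per angle bin, with per-cell bin
#' fractions as the observations, and a two-sample Kolmogorov-Smirnov test
#' on the pooled per-pixel angle distributions. No multiple-testing
#' correction is applied across bins (matching the reporting convention
#' the tests come from); a Bonferroni-adjusted column is provided
#' alongside, clearly labeled.
#'
#' @param hists_a,hists_b Lists of per-cell `directionality_histogram`s
#'   (same bins); at least two cells per group for the t-tests.
#' @param angles_a,angles_b Optional pooled per-pixel angle vectors for
#'   the K-S test; when omitted, the K-S test is skipped.
#' @return A `group_comparison`: list with `per_bin` (data frame `bin_lo`,
#'   `bin_hi`, `mean_a`, `mean_b`, `t_stat`, `p`, `p_bonferroni`), `ks`
#'   (statistic and p-value or `NULL`), `effect_bin0` (mean_a - mean_b in
#'   the parallel 0-10 bin), `n_cells`, and `t_test_error` (message when
#'   a group has fewer than two cells; K-S is still computed).
#' @export
compare_directionality <- function(hists_a, hists_b,
                                   angles_a = NULL, angles_b = NULL) {
  frac <- function(hists) vapply(hists, function(h) h$fraction,
                                 numeric(nrow(hists[[1]])))
  bins <- hists_a[[1]][c("bin_lo", "bin_hi")]
  fa <- frac(hists_a); fb <- frac(hists_b)
  n_a <- ncol(fa); n_b <- ncol(fb)

  per_bin <- NULL
  t_err <- NULL
  if (n_a < 2 || n_b < 2) {
    t_err <- "per-bin t-tests need at least two cells per group"
  } else {
    res <- lapply(seq_len(nrow(bins)), function(k) {
      a <- fa[k, ]; b <- fb[k, ]
      tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      if (is.null(tt)) {
        # degenerate variance: report as computed, with a warning
        warning(sprintf("degenerate variance in bin %g-%g",
                        bins$bin_lo[k], bins$bin_hi[k]), call. = FALSE)
        list(stat = if (mean(a) == mean(b)) 0 else NaN,
             p = if (mean(a) == mean(b)) 1 else NaN)
      } else {
        list(stat = unname(tt$statistic), p = tt$p.value)
      }
    })
    per_bin <- data.frame(bins,
                          mean_a = rowMeans(fa), mean_b = rowMeans(fb),
                          t_stat = vapply(res, `[[`, numeric(1), "stat"),
                          p = vapply(res, `[[`, numeric(1), "p"))
    per_bin$p_bonferroni <- pmin(per_bin$p * nrow(per_bin), 1)
  }

  ks <- NULL
  if (!is.null(angles_a) && !is.null(angles_b)) {
    ks_res <- suppressWarnings(stats::ks.test(angles_a, angles_b))
    ks <- list(statistic = unname(ks_res$statistic), p = ks_res$p.value)
  }
  bin0 <- 1L
  structure(list(per_bin = per_bin, ks = ks,
                 effect_bin0 = mean(fa[bin0, ]) - mean(fb[bin0, ]),
                 n_cells = c(a = n_a, b = n_b),
                 t_test_error = t_err),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison: %d vs %d cells\n",
              x$n_cells["a"], x$n_cells["b"]))
  if (!is.null(x$t_test_error)) {
    cat("  t-tests: ", x$t_test_error, "\n", sep = "")
  } else {
    print.data.frame(x$per_bin, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$ks)) {
    cat(sprintf("  K-S on pooled angles: D = %.4f, p = %.3g\n",
                x$ks$statistic, x$ks$p))
  }
  cat(sprintf("  parallel-bin effect (A - B): %+.3f\n", x$effect_bin0))
  invisible(x)
}
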