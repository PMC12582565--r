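# The standard synthetic study reused by the acceptance-level tests:
# 10 cells of mixed smooth shapes, rendered once with border-parallel and
# once with isotropic filament populations, analyzed with the default
# chain (RL deconvolution, per-cell perfect threshold). Cached so several
# test blocks can share one computation.
acceptance_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    shapes <- rep(c("ellipse", "superellipse", "smoothed_polygon"),
                  length.out = 10)
    sizes <- list(c(15, 10), c(12, 9), c(14, 11), c(10, 10), c(13, 8))
    par_h <- list(); iso_h <- list()
    par_ang <- list(); iso_ang <- list()
    for (k in 1:10) {
      m <- generate_cell_mask(shapes[k], sizes[[(k - 1) %% 5 + 1]],
                              seed = 100 + k)
      rp <- render_mt_image(m, filament_spec(n_filaments = 60),
                            seed = 200 + k)
      dp <- directionality_analysis(rp$image, m,
                                    threshold_mode = "perfect",
                                    cell_id = paste0("par", k))
      par_h[[k]] <- dp$histogram
      sel <- !is.na(unclass(dp$angles)) & !is.na(dp$geometry$distance_um) &
        dp$geometry$distance_um < 1
      par_ang[[k]] <- unclass(dp$angles)[sel]

      ri <- render_mt_image(m, filament_spec(
        n_filaments = 60, orientation_model = "isotropic"),
        seed = 300 + k)
      di <- directionality_analysis(ri$image, m,
                                    threshold_mode = "perfect",
                                    cell_id = paste0("iso", k))
      iso_h[[k]] <- di$histogram
      sel <- !is.na(unclass(di$angles)) & !is.na(di$geometry$distance_um) &
        di$geometry$distance_um < 1
      iso_ang[[k]] <- unclass(di$angles)[sel]
    }
    cache <<- list(parallel_hists = par_h, isotropic_hists = iso_h,
                   parallel_angles = unlist(par_ang),
                   isotropic_angles = unlist(iso_ang))
    cache
  }
})
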