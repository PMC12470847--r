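# Shared fixtures, built once per test run and cached. The coarse raster
# (0.5 deg/sample) keeps unit tests fast; the analysis raster (0.25) is
# used where fitting accuracy is the thing under test.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  val <- switch(name,
    ap_coarse = build_run_apertures(grid = field_grid(7.5, 0.5)),
    model_coarse = prf_model(fixture("ap_coarse")),
    gridpred_coarse = grid_predictions(
      fixture("model_coarse"),
      prf_search_grid(n_ecc = 8, n_angle = 12, n_sigma = 8)),
    ap = build_run_apertures(grid = field_grid(7.5, 0.25)),
    model = prf_model(fixture("ap")),
    gridpred = grid_predictions(fixture("model")),
    stop("unknown fixture: ", name))
  .fixture_cache[[name]] <- val
  val
}

# A minimal aperture_sequence with hand-chosen frames on a given grid,
# for operations that only need grid + frames.
toy_apertures <- function(grid, frames, mapping_idx = seq_len(ncol(frames))) {
  structure(list(grid = grid, frames = frames,
                 annotation = rep("bar", ncol(frames)),
                 mapping_idx = mapping_idx,
                 design = run_design(), geom = mask_geometry()),
            class = "aperture_sequence")
}

# Random vertex position inside the stimulated region (clear of the
# occluded meridian wedges), mirroring where mapped vertices live.
draw_stim_position <- function(n, ecc_range = c(0, 7)) {
  u <- runif(n)
  ang <- ifelse(runif(n) < 0.5, -80 + 160 * u, 100 + 160 * u)
  ecc <- runif(n, ecc_range[1], ecc_range[2])
  data.frame(ecc = ecc, ang = ang,
             x0 = ecc * cos(ang * pi / 180), y0 = ecc * sin(ang * pi / 180))
}
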