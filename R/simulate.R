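# Ground-truthed synthetic fMRI datasets: multi-run BOLD per vertex under
# the two adapter conditions, with oracle effective pRF sizes attached.

#' Configuration of the synthetic fMRI dataset
#'
#' Defaults emulate the study conditions: 8 participants, an even run count
#' (half with the high-SF adapter in the vertex's hemifield, half with the
#' low-SF adapter; 8 runs is the middle of the reported 6--10 range),
#' eccentricities inside the mapped annulus, suppression amplitude 0.5
#' with 1-octave bandwidth, and additive iid Gaussian noise calibrated as
#' a multiple of the clean per-run signal SD. With 4 runs per condition
#' the odd/even halves average 2 runs each, so the half-average
#' reliability is `1 / (1 + noise_rel^2 / 2)`; the default 0.93 puts the
#' split-half r near 0.7, typical of surface-vertex data.
#'
#' @param n_participants simulated participants.
#' @param n_vertices vertices per participant.
#' @param n_runs runs per participant; must be even.
#' @param ecc_range eccentricity range of nominal vertex positions, deg.
#' @param rois named list; each entry may override `size_a` / `size_b` of
#'   the population config (one simulated "visual area" by default).
#' @param adaptation an [adaptation_model()].
#' @param population a [population_config()].
#' @param noise_rel noise SD as a multiple of the clean run SD.
#' @param grid_resolution simulation/fitting raster, deg per sample.
#' @param amplitude,baseline affine BOLD scaling passed to
#'   [bold_from_neural()].
#' @param compute_truth store oracle effective sigmas (slower).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 8, n_vertices = 300, n_runs = 8,
                       ecc_range = c(0.5, 7),
                       rois = list(V1 = list()),
                       adaptation = adaptation_model(),
                       population = population_config(),
                       noise_rel = 0.93,
                       grid_resolution = 0.25,
                       amplitude = 1, baseline = 0,
                       compute_truth = TRUE) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_runs %% 2 != 0)
    stop("n_runs must be even (equal counts of the two adapter layouts)")
  if (cfg$n_runs < 2) stop("need at least 2 runs")
  if (cfg$noise_rel < 0) stop("noise_rel must be >= 0")
  if (length(cfg$rois) < 1 || is.null(names(cfg$rois)))
    stop("rois must be a named list")
  stopifnot(inherits(cfg$adaptation, "adaptation_model"),
            inherits(cfg$population, "population_config"))
  invisible(cfg)
}

# Random polar angle inside a hemifield, clear of the meridian wedges.
draw_angle <- function(hemifield, wedge_half = 10) {
  if (hemifield == "right") runif(1, -90 + wedge_half, 90 - wedge_half)
  else runif(1, 90 + wedge_half, 270 - wedge_half)
}

#' Simulate a full multi-participant pRF dataset
#'
#' For every vertex, a subunit population is drawn, its condition-specific
#' gains computed, and `n_runs / 2` noisy BOLD runs generated per adapter
#' condition (a vertex's condition is the adapter SF shown in its
#' hemifield; alternating HL/LH runs give each condition half the runs).
#' Identical seeds give bit-identical datasets.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param apertures optional pre-built [build_run_apertures()] on the
#'   matching grid (rebuilt if `NULL`).
#' @return object of class `prf_dataset`: `vertices` (one row per vertex:
#'   participant, roi, hemifield, nominal position, truth sigmas), `bold`
#'   (per vertex, per condition: time x run matrix), plus the apertures,
#'   HRF kernel and config.
#' @export
simulate_fmri_dataset <- function(cfg = sim_config(), seed = 1,
                                  apertures = NULL) {
  validate_sim_config(cfg)
  set.seed(stage_seed(seed, "simulate-fmri"))
  if (is.null(apertures))
    apertures <- build_run_apertures(
      grid = field_grid(7.5, cfg$grid_resolution))
  kernel <- hrf_kernel(tr = apertures$design$tr)
  runs_per_cond <- cfg$n_runs / 2
  n_time <- ncol(apertures$frames)
  conds <- names(cfg$adaptation$adapter_sf)
  roi_names <- names(cfg$rois)

  rows <- vector("list", cfg$n_participants * cfg$n_vertices)
  bold <- vector("list", length(rows))
  k <- 0
  for (p in seq_len(cfg$n_participants)) {
    for (v in seq_len(cfg$n_vertices)) {
      k <- k + 1
      roi <- roi_names[((v - 1) %% length(roi_names)) + 1]
      pop_cfg <- cfg$population
      for (fld in intersect(names(cfg$rois[[roi]]), c("size_a", "size_b")))
        pop_cfg[[fld]] <- cfg$rois[[roi]][[fld]]
      hemifield <- sample(c("left", "right"), 1)
      ecc <- runif(1, cfg$ecc_range[1], cfg$ecc_range[2])
      ang <- draw_angle(hemifield)
      pop <- sample_population(ecc, ang, pop_cfg)

      truth <- list()
      runs <- list()
      for (cond in conds) {
        gains <- population_gains(pop, cond, cfg$adaptation)
        neural <- neural_timecourse(pop, apertures, gains)
        clean <- cfg$amplitude * convolve_hrf(neural, kernel) + cfg$baseline
        noise_sd <- cfg$noise_rel * sd(clean)
        runs[[cond]] <- clean +
          matrix(rnorm(n_time * runs_per_cond, 0, noise_sd),
                 n_time, runs_per_cond)
        if (cfg$compute_truth)
          truth[[cond]] <- effective_sigma_oracle(
            pop, cond, apertures$grid, cfg$adaptation)
      }
      bold[[k]] <- runs
      rows[[k]] <- data.frame(
        participant = p, vertex_id = k, roi = roi, hemifield = hemifield,
        ecc = ecc, angle = ang,
        truth_sigma_high = if (cfg$compute_truth) truth$high_adapted$sigma else NA_real_,
        truth_sigma_low = if (cfg$compute_truth) truth$low_adapted$sigma else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(
    vertices = do.call(rbind, rows),
    bold = bold,
    apertures = apertures,
    hrf_kernel = kernel,
    cfg = cfg,
    seed = seed
  ), class = "prf_dataset")
}

#' @export
print.prf_dataset <- function(x, ...) {
  cat(sprintf(
    "<prf_dataset> %d participants x %d vertices, %d runs (%d per condition), A = %g, w = %g oct\n",
    x$cfg$n_participants, x$cfg$n_vertices, x$cfg$n_runs, x$cfg$n_runs / 2,
    x$cfg$adaptation$amplitude, x$cfg$adaptation$bandwidth))
  invisible(x)
}
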