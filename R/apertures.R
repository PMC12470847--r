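# Visual-field geometry and per-TR binary bar apertures for a mapping run.
#
# Conventions: x positive rightward, y positive upward, origin at fixation,
# units are degrees of visual angle. A pixel belongs to a region when its
# centre satisfies the defining inequality, half-open so that left/right
# hemifield masks are exact mirror images and rotations by multiples of 90
# degrees map the sample lattice onto itself.

#' Square sampling grid over the visual field
#'
#' @param half_extent half width/height of the field in degrees (the mapped
#'   aperture has radius 7.5 deg, so the default grid spans \[-7.5, 7.5\]).
#' @param resolution sample spacing in degrees; must divide `half_extent`.
#' @return object of class `field_grid`: axis values, flattened pixel
#'   coordinate vectors `x`, `y` (x varies fastest), and sizes.
#' @examples
#' g <- field_grid(7.5, 0.1)  # 151 x 151 samples
#' @export
field_grid <- function(half_extent = 7.5, resolution = 0.1) {
  if (!is.numeric(half_extent) || half_extent <= 0)
    stop("half_extent must be positive")
  if (!is.numeric(resolution) || resolution <= 0 || resolution > half_extent)
    stop("resolution must be in (0, half_extent]")
  n_half <- half_extent / resolution
  if (abs(n_half - round(n_half)) > 1e-8)
    stop("half_extent must be an integer multiple of resolution")
  n_half <- round(n_half)
  axis <- (-n_half:n_half) * resolution  # exactly symmetric about 0
  n <- length(axis)
  structure(list(
    axis = axis,
    x = rep(axis, times = n),
    y = rep(axis, each = n),
    n_side = n,
    n_pix = n * n,
    half_extent = half_extent,
    resolution = resolution
  ), class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %d x %d samples, [%g, %g] deg, %g deg/sample\n",
              x$n_side, x$n_side, -x$half_extent, x$half_extent, x$resolution))
  invisible(x)
}

#' Stimulus mask geometry
#'
#' The adapters (and hence the mapping bars, which are occluded wherever the
#' adapter was not shown) cover an annulus bounded by the circular aperture
#' and a central occluder, minus two wedges centred on the upper and lower
#' vertical meridian.
#'
#' @param aperture_radius outer radius, deg (7.5 for the fMRI display,
#'   7.7 for psychophysics).
#' @param central_occluder_diameter diameter of the central gray disc, deg
#'   (0.7 fMRI; 2.0 psychophysics).
#' @param wedge_full_width full polar-angle width of each meridian wedge, deg.
#' @return object of class `mask_geometry`.
#' @export
mask_geometry <- function(aperture_radius = 7.5,
                          central_occluder_diameter = 0.7,
                          wedge_full_width = 20) {
  if (central_occluder_diameter <= 0 ||
      central_occluder_diameter >= 2 * aperture_radius)
    stop("central_occluder_diameter must be in (0, 2 * aperture_radius)")
  if (wedge_full_width < 0 || wedge_full_width >= 180)
    stop("wedge_full_width must be in [0, 180)")
  structure(list(
    aperture_radius = aperture_radius,
    central_occluder_diameter = central_occluder_diameter,
    wedge_full_width = wedge_full_width
  ), class = "mask_geometry")
}

#' Binary mask of the adapter-covered region
#'
#' A pixel is inside when `occluder_radius <= r < aperture_radius`, it lies
#' outside both vertical-meridian wedges, and it is in the requested
#' hemifield. Left and right masks are exact mirror images (x -> -x).
#'
#' @param grid a [field_grid()].
#' @param geom a [mask_geometry()].
#' @param hemifield one of `"both"`, `"left"`, `"right"`.
#' @return integer vector of length `grid$n_pix` with values in \{0, 1\}.
#' @export
adapter_region_mask <- function(grid, geom, hemifield = c("both", "left", "right")) {
  hemifield <- match.arg(hemifield)
  stopifnot(inherits(grid, "field_grid"), inherits(geom, "mask_geometry"))
  r <- sqrt(grid$x^2 + grid$y^2)
  keep <- r < geom$aperture_radius & r >= geom$central_occluder_diameter / 2
  if (geom$wedge_full_width > 0) {
    theta <- atan2(grid$y, grid$x) * 180 / pi          # (-180, 180]
    d_up <- abs(theta - 90)
    d_down <- pmin(abs(theta + 90), abs(theta - 270))  # wrap-safe
    keep <- keep & d_up >= geom$wedge_full_width / 2 &
      d_down >= geom$wedge_full_width / 2
  }
  if (hemifield == "left") keep <- keep & grid$x < 0
  if (hemifield == "right") keep <- keep & grid$x > 0
  as.integer(keep)
}

#' Binary mask of one bar position
#'
#' Sweep 0 moves bottom to top (a horizontal bar); each subsequent sweep is
#' the previous one rotated 45 degrees clockwise (screen convention, y up:
#' the motion-direction angle decreases by 45 degrees per sweep). The 25
#' half-overlapping steps are symmetric about fixation along the motion
#' axis: centre of step `s` (0-based) sits at `(s - (n-1)/2) * bar_width/2`,
#' so the middle step is centred on the fixation-orthogonal axis and the
#' centre travel spans `(n-1) * bar_width/2` = 13.8 deg for the defaults.
#' The bar is unbounded lengthwise; the adapter-region mask truncates it.
#'
#' @param grid a [field_grid()].
#' @param sweep sweep index 0..7.
#' @param step step index 0..`n_steps - 1`.
#' @param bar_width bar width in deg.
#' @param n_steps number of bar steps per sweep.
#' @return integer vector of length `grid$n_pix` with values in \{0, 1\}.
#' @export
bar_mask <- function(grid, sweep, step, bar_width = 1.15, n_steps = 25) {
  stopifnot(inherits(grid, "field_grid"))
  if (length(sweep) != 1 || sweep < 0 || sweep > 7 || sweep != round(sweep))
    stop("sweep must be an integer in 0..7")
  if (length(step) != 1 || step < 0 || step > n_steps - 1 || step != round(step))
    stop(sprintf("step must be an integer in 0..%d", n_steps - 1))
  # cospi/sinpi give exact 0/±1 on the cardinal directions, keeping the
  # half-open bar boundary independent of the orthogonal coordinate
  dir <- (90 - 45 * sweep) / 180
  u <- grid$x * cospi(dir) + grid$y * sinpi(dir)  # position along motion axis
  centre <- (step - (n_steps - 1) / 2) * bar_width / 2
  as.integer(u >= centre - bar_width / 2 & u < centre + bar_width / 2)
}

#' Timing and geometry of one pRF mapping run
#'
#' A run is 25 volumes of baseline, 30 volumes of initial adaptation, eight
#' 25-volume bar sweeps with one 25-volume blank after sweep 4 and one after
#' sweep 8, and 25 volumes of closing baseline: 330 volumes at TR = 1 s, of
#' which the 250 between the initial adaptation and the closing baseline
#' (bars plus blanks) are the mapping volumes used for fitting.
#'
#' @param tr repetition time, s.
#' @param n_baseline_pre,n_adapt,n_baseline_post block lengths in volumes.
#' @param n_sweeps number of bar sweeps.
#' @param n_bar_steps bar steps (= volumes) per sweep.
#' @param blank_after sweep indices after which a blank block is inserted.
#' @param blank_len blank block length in volumes.
#' @param bar_width bar width, deg.
#' @return object of class `run_design`.
#' @export
run_design <- function(tr = 1, n_baseline_pre = 25, n_adapt = 30,
                       n_sweeps = 8, n_bar_steps = 25,
                       blank_after = c(4, 8), blank_len = 25,
                       n_baseline_post = 25, bar_width = 1.15) {
  d <- structure(list(
    tr = tr, n_baseline_pre = n_baseline_pre, n_adapt = n_adapt,
    n_sweeps = n_sweeps, n_bar_steps = n_bar_steps,
    blank_after = blank_after, blank_len = blank_len,
    n_baseline_post = n_baseline_post, bar_width = bar_width
  ), class = "run_design")
  d$n_mapping <- n_sweeps * n_bar_steps + length(blank_after) * blank_len
  d$n_total <- n_baseline_pre + n_adapt + d$n_mapping + n_baseline_post
  d
}

#' Build the annotated aperture sequence for a full run
#'
#' Bar frames are the intersection of the bar mask with the adapter region
#' over both hemifields; baseline, adaptation and blank frames are all-zero
#' (the adapters stimulate the same region in every volume, so their
#' contribution is constant over the time series and is not modelled).
#'
#' @param design a [run_design()].
#' @param geom a [mask_geometry()].
#' @param grid a [field_grid()].
#' @return object of class `aperture_sequence`: `frames` is an
#'   `n_pix x n_total` 0/1 matrix, `annotation` a character vector
#'   (`"baseline"`, `"adaptation"`, `"blank"`, `"bar(sweep,step)"`), and
#'   `mapping_idx` the indices of the 250 mapping volumes.
#' @export
build_run_apertures <- function(design = run_design(),
                                geom = mask_geometry(),
                                grid = field_grid()) {
  stopifnot(inherits(design, "run_design"))
  region <- adapter_region_mask(grid, geom, "both")
  frames <- matrix(0, nrow = grid$n_pix, ncol = design$n_total)
  annotation <- character(design$n_total)
  t0 <- 0
  annotation[t0 + seq_len(design$n_baseline_pre)] <- "baseline"
  t0 <- t0 + design$n_baseline_pre
  annotation[t0 + seq_len(design$n_adapt)] <- "adaptation"
  t0 <- t0 + design$n_adapt
  mapping_start <- t0 + 1
  for (sw in seq_len(design$n_sweeps)) {
    for (st in seq_len(design$n_bar_steps)) {
      t0 <- t0 + 1
      frames[, t0] <- bar_mask(grid, sw - 1, st - 1,
                               design$bar_width, design$n_bar_steps) * region
      annotation[t0] <- sprintf("bar(%d,%d)", sw - 1, st - 1)
    }
    if (sw %in% design$blank_after) {
      annotation[t0 + seq_len(design$blank_len)] <- "blank"
      t0 <- t0 + design$blank_len
    }
  }
  mapping_idx <- mapping_start:t0
  annotation[t0 + seq_len(design$n_baseline_post)] <- "baseline"
  structure(list(
    grid = grid, geom = geom, design = design,
    frames = frames, annotation = annotation,
    mapping_idx = mapping_idx
  ), class = "aperture_sequence")
}

#' @export
print.aperture_sequence <- function(x, ...) {
  cat(sprintf(
    "<aperture_sequence> %d frames (%d mapping), %d x %d grid, %d bar frames\n",
    ncol(x$frames), length(x$mapping_idx), x$grid$n_side, x$grid$n_side,
    sum(startsWith(x$annotation, "bar"))))
  invisible(x)
}

#' Geometric mean of two spatial frequencies
#'
#' The mid-SF mapping/reference stimulus sits at the geometric mean of the
#' low (0.5 cpd) and high (3.5 cpd) adapter frequencies, ~1.3 cpd, i.e.
#' equidistant from both adapters in log (octave) space.
#'
#' @param f1,f2 spatial frequencies in cycles/deg, positive.
#' @return `sqrt(f1 * f2)` in cpd.
#' @examples
#' geometric_mean_sf(0.5, 3.5)  # ~1.32 cpd
#' @export
geometric_mean_sf <- function(f1, f2) {
  if (any(f1 <= 0) || any(f2 <= 0)) stop("spatial frequencies must be positive")
  sqrt(f1 * f2)
}
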