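# Neural-subpopulation simulator: a vertex is a mixture of Gaussian
# receptive subfields whose size is inversely linked to preferred spatial
# frequency; adapter-tuned gain suppression reshapes the gain-weighted
# aggregate, which is what the pRF estimator sees.

#' Adaptation gain model
#'
#' Gain suppression is Gaussian in octave (log2 SF) distance from the
#' adapter: `g = 1 - A * exp(-log2(pref/adapter)^2 / (2 w^2))`, so a neuron
#' tuned exactly to the adapter keeps gain `1 - A` and neurons more than a
#' couple of octaves away are essentially unaffected, in line with the
#' reported ~2-octave spread of SF adaptation.
#'
#' @param amplitude suppression amplitude `A` in \[0, 1).
#' @param bandwidth tuning bandwidth `w` in octaves, > 0.
#' @param adapter_sf named adapter SFs (cpd) per condition.
#' @return object of class `adaptation_model`.
#' @export
adaptation_model <- function(amplitude = 0.5, bandwidth = 1,
                             adapter_sf = c(high_adapted = 3.5,
                                            low_adapted = 0.5)) {
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must be in [0, 1)")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (any(adapter_sf <= 0)) stop("adapter SFs must be positive")
  structure(list(amplitude = amplitude, bandwidth = bandwidth,
                 adapter_sf = adapter_sf), class = "adaptation_model")
}

#' Post-adaptation response gain of one neuron
#'
#' @param pref_sf preferred SF, cpd.
#' @param adapter_sf adapter SF, cpd.
#' @param model an [adaptation_model()].
#' @return gain in `[1 - A, 1]`; symmetric in octave distance.
#' @export
adaptation_gain <- function(pref_sf, adapter_sf, model = adaptation_model()) {
  if (any(pref_sf <= 0) || any(adapter_sf <= 0))
    stop("spatial frequencies must be positive")
  d <- log2(pref_sf / adapter_sf)
  1 - model$amplitude * exp(-d^2 / (2 * model$bandwidth^2))
}

#' Configuration of the subunit generator
#'
#' Subunit RF sizes are log-normal with median `size_a + size_b * ecc`
#' (the familiar linear size-eccentricity scaling); `size_sdlog` sets the
#' within-vertex size heterogeneity that the adaptation effect feeds on.
#' Preferred SF is tied to size by `pref_sf = sf_size_constant / rf_size`,
#' so with the default 0.65 cpd deg a 0.5 deg subfield prefers the 1.3 cpd
#' mapping SF. Centres scatter isotropically around the nominal position
#' with SD `scatter_coef * median size`.
#'
#' @param n_subunits subunits per vertex.
#' @param size_a,size_b intercept (deg) and slope (deg/deg) of the median
#'   RF size against eccentricity.
#' @param size_sdlog log-normal SD of subunit sizes.
#' @param scatter_coef centre scatter as a fraction of the median size.
#' @param sf_size_constant `pref_sf * rf_size` product, cpd deg.
#' @return list of class `population_config`.
#' @export
population_config <- function(n_subunits = 20, size_a = 0.25, size_b = 0.12,
                              size_sdlog = 0.5, scatter_coef = 0.25,
                              sf_size_constant = 0.65) {
  if (n_subunits < 1) stop("n_subunits must be >= 1")
  if (size_a <= 0 || size_b < 0) stop("invalid size scaling")
  if (size_sdlog < 0 || scatter_coef < 0) stop("invalid spread parameters")
  if (sf_size_constant <= 0) stop("sf_size_constant must be positive")
  structure(list(n_subunits = n_subunits, size_a = size_a, size_b = size_b,
                 size_sdlog = size_sdlog, scatter_coef = scatter_coef,
                 sf_size_constant = sf_size_constant),
            class = "population_config")
}

#' Draw the neural subpopulation of one vertex
#'
#' @param nominal_ecc,nominal_angle nominal position (deg, deg polar angle
#'   counterclockwise from the positive x axis).
#' @param cfg a [population_config()].
#' @return object of class `neural_population`: a data frame of subunits
#'   (`x`, `y`, `rf_size`, `pref_sf`, `base_gain`) plus the nominal
#'   position. `pref_sf * rf_size` equals `sf_size_constant` exactly by
#'   construction.
#' @export
sample_population <- function(nominal_ecc, nominal_angle,
                              cfg = population_config()) {
  stopifnot(inherits(cfg, "population_config"))
  if (nominal_ecc < 0) stop("eccentricity must be >= 0")
  med <- cfg$size_a + cfg$size_b * nominal_ecc
  n <- cfg$n_subunits
  rf_size <- rlnorm(n, meanlog = log(med), sdlog = cfg$size_sdlog)
  a <- nominal_angle * pi / 180
  cx <- nominal_ecc * cos(a)
  cy <- nominal_ecc * sin(a)
  sc <- cfg$scatter_coef * med
  sub <- data.frame(
    x = cx + rnorm(n, 0, sc),
    y = cy + rnorm(n, 0, sc),
    rf_size = rf_size,
    pref_sf = cfg$sf_size_constant / rf_size,
    base_gain = 1
  )
  structure(list(subunits = sub, nominal_ecc = nominal_ecc,
                 nominal_angle = nominal_angle, cfg = cfg),
            class = "neural_population")
}

# Per-subunit gains for a named condition under an adaptation model.
population_gains <- function(pop, condition, model) {
  stopifnot(inherits(pop, "neural_population"))
  adapter <- model$adapter_sf[[condition]]
  pop$subunits$base_gain *
    adaptation_gain(pop$subunits$pref_sf, adapter, model)
}

#' Ground-truth effective pRF size of a population
#'
#' The oracle against which pipeline recovery is judged: the gain-weighted
#' sum of unit-volume subunit Gaussians is rendered on the grid and the
#' best-fitting single scaled 2D Gaussian (least squares, amplitude
#' profiled out, Nelder-Mead over centre and SD) gives the effective
#' sigma. With suppression off this reduces to the subunit mixture itself;
#' for a single subunit it returns that subunit's own size and centre.
#'
#' @param pop a [sample_population()].
#' @param condition condition name matched against the model's adapter SFs,
#'   or `NULL` for no adaptation.
#' @param grid a [field_grid()].
#' @param model an [adaptation_model()].
#' @return list with `sigma`, `x0`, `y0` of the best single-Gaussian fit.
#' @export
effective_sigma_oracle <- function(pop, condition = NULL,
                                   grid = field_grid(7.5, 0.25),
                                   model = adaptation_model()) {
  gains <- if (is.null(condition)) pop$subunits$base_gain
           else population_gains(pop, condition, model)
  if (all(gains <= 0)) stop("all subunit gains are zero")
  img <- aggregate_profile(pop, gains, grid)
  sub <- pop$subunits
  w <- gains / sum(gains)
  init <- c(sum(w * sub$x), sum(w * sub$y),
            exp(sum(w * log(sub$rf_size))))
  obj <- function(p) cpp_gauss_image_rss(img, grid$x, grid$y, p[1], p[2], p[3])
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  # one restart guards against premature simplex collapse
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  list(x0 = fit$par[1], y0 = fit$par[2], sigma = abs(fit$par[3]))
}

# Gain-weighted aggregate spatial profile on the grid. Each subunit enters
# with unit volume (its overlap response is normalised by its own mass), so
# weighting is purely by gain.
aggregate_profile <- function(pop, gains, grid) {
  sub <- pop$subunits
  img <- numeric(grid$n_pix)
  for (i in seq_len(nrow(sub))) {
    if (gains[i] <= 0) next
    g <- cpp_gauss_field(grid$x, grid$y, sub$x[i], sub$y[i], sub$rf_size[i])
    s <- sum(g)
    if (s > 0) img <- img + gains[i] * g / s
  }
  img
}

#' Neural response of a population to an aperture sequence
#'
#' Each subunit responds with its normalised Gaussian overlap with the
#' frame (0 for an empty frame, 1 for full field), scaled by its gain; the
#' vertex response is the subunit mean, so a full-field frame returns the
#' mean gain.
#'
#' @param pop a [sample_population()].
#' @param gains per-subunit gains (e.g. from a condition), default base.
#' @param apertures an [build_run_apertures()] sequence on the same grid.
#' @return numeric series of length `ncol(apertures$frames)`.
#' @export
neural_timecourse <- function(pop, apertures, gains = pop$subunits$base_gain) {
  stopifnot(inherits(apertures, "aperture_sequence"))
  if (length(gains) != nrow(pop$subunits))
    stop("gains must match the number of subunits")
  w <- aggregate_profile(pop, gains, apertures$grid) / nrow(pop$subunits)
  as.numeric(crossprod(apertures$frames, w))
}

#' BOLD run from a neural series
#'
#' @param series neural series.
#' @param kernel HRF kernel from [hrf_kernel()].
#' @param amplitude,baseline affine response scaling.
#' @param noise_sd SD of iid Gaussian noise added per sample (>= 0).
#' @return numeric series of the same length.
#' @export
bold_from_neural <- function(series, kernel, amplitude = 1, baseline = 0,
                             noise_sd = 0) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  clean <- amplitude * convolve_hrf(series, kernel) + baseline
  clean + rnorm(length(series), 0, noise_sd)
}
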