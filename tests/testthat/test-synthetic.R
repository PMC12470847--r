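# Neural-population generator, adaptation gains, oracle sigmas, BOLD
# simulation, and the simulated observer.

test_that("adaptation gain: closed form, bounds, symmetry in octave distance", {
  m <- adaptation_model(amplitude = 0.6, bandwidth = 1)
  expect_equal(adaptation_gain(3.5, 3.5, m), 1 - 0.6)       # at the adapter
  expect_equal(adaptation_gain(2, 7, adaptation_model(amplitude = 0)), 1)
  # 4 octaves out with w = 1: 1 - A exp(-8)
  expect_equal(adaptation_gain(16, 1, m), 1 - 0.6 * exp(-8))
  set.seed(1)
  for (i in 1:20) {
    f <- runif(1, 0.2, 4); d <- runif(1, 0.1, 3)
    expect_equal(adaptation_gain(f * 2^d, f, m),
                 adaptation_gain(f * 2^-d, f, m))
    g <- adaptation_gain(runif(1, 0.1, 10), f, m)
    expect_true(g >= 1 - 0.6 && g <= 1)
  }
  expect_error(adaptation_gain(-1, 1, m), "positive")
})

test_that("population sampling: degenerate case, size-SF link, median scaling", {
  set.seed(2)
  cfg0 <- population_config(n_subunits = 1, scatter_coef = 0, size_sdlog = 0)
  pop <- sample_population(3, 45, cfg0)
  expect_equal(pop$subunits$x, 3 * cos(pi / 4))
  expect_equal(pop$subunits$y, 3 * sin(pi / 4))
  expect_equal(pop$subunits$rf_size, 0.25 + 0.12 * 3)

  # pref_sf * rf_size = c exactly for every subunit, by construction
  big <- sample_population(4, 10, population_config(n_subunits = 500))
  expect_equal(big$subunits$pref_sf * big$subunits$rf_size,
               rep(0.65, 500))

  # sample median of rf_size over many draws ~ a + b * ecc
  huge <- sample_population(5, 0, population_config(n_subunits = 1e5))
  expect_equal(median(huge$subunits$rf_size), 0.25 + 0.12 * 5,
               tolerance = 0.02)
  expect_error(population_config(n_subunits = 0))
})

test_that("effective sigma oracle: exact cases and adaptation direction", {
  grid <- field_grid(7.5, 0.25)
  set.seed(3)
  pop1 <- sample_population(
    3, 0, population_config(n_subunits = 1, scatter_coef = 0, size_sdlog = 0))
  o <- effective_sigma_oracle(pop1, NULL, grid)
  expect_equal(o$sigma, pop1$subunits$rf_size, tolerance = 1e-4)
  expect_equal(o$x0, 3, tolerance = 1e-4)
  expect_equal(o$y0, 0, tolerance = 1e-4)

  # two identical-size subunits at the same centre give that size
  pop2 <- pop1
  pop2$subunits <- rbind(pop1$subunits, pop1$subunits)
  o2 <- effective_sigma_oracle(pop2, NULL, grid)
  expect_equal(o2$sigma, pop1$subunits$rf_size, tolerance = 1e-4)

  # mixed small + large subunits: strong high-SF adaptation silences the
  # small-RF (high-SF-preferring) units, so the aggregate broadens
  pop_mix <- pop1
  pop_mix$subunits <- data.frame(
    x = c(3, 3), y = c(0, 0), rf_size = c(0.3, 1.2),
    pref_sf = 0.65 / c(0.3, 1.2), base_gain = 1)
  m <- adaptation_model(amplitude = 0.8, bandwidth = 1)
  sh <- effective_sigma_oracle(pop_mix, "high_adapted", grid, m)$sigma
  sl <- effective_sigma_oracle(pop_mix, "low_adapted", grid, m)$sigma
  expect_gt(sh, sl)

  # no suppression: invariant to the adapter SF
  m0 <- adaptation_model(amplitude = 0)
  expect_equal(effective_sigma_oracle(pop_mix, "high_adapted", grid, m0)$sigma,
               effective_sigma_oracle(pop_mix, "low_adapted", grid, m0)$sigma)
})

test_that("zero-gain population is rejected", {
  pop <- sample_population(2, 0, population_config(n_subunits = 2))
  pop$subunits$base_gain <- 0
  expect_error(effective_sigma_oracle(pop, NULL), "gains")
})

test_that("neural timecourse: empty and full-field frames, strip oracle", {
  grid <- field_grid(7.5, 0.1)
  frames <- cbind(rep(0, grid$n_pix), rep(1, grid$n_pix))
  ap <- toy_apertures(grid, frames)
  set.seed(4)
  pop <- sample_population(2, 20, population_config(n_subunits = 5))
  gains <- c(0.3, 1, 0.7, 0.5, 1)
  r <- neural_timecourse(pop, ap, gains)
  expect_equal(r[1], 0)
  expect_equal(r[2], mean(gains))  # full field -> mean gain

  # single subunit at (3, 0), sigma 0.5, vertical strip x in [2.7, 3.3):
  # response = Gaussian mass in the strip (y fully covered)
  pop1 <- sample_population(
    3, 0, population_config(n_subunits = 1, scatter_coef = 0, size_sdlog = 0))
  pop1$subunits$rf_size <- 0.5
  strip <- as.integer(grid$x >= 2.7 & grid$x < 3.3)
  ap1 <- toy_apertures(grid, cbind(strip))
  got <- neural_timecourse(pop1, ap1)
  # independent fine-raster oracle for the same half-open strip: midpoint
  # sum of the 1D Gaussian over the covered pixel columns
  cols <- grid$axis[grid$axis >= 2.7 & grid$axis < 3.3]
  oracle <- sum(dnorm(cols, 3, 0.5)) / sum(dnorm(grid$axis, 3, 0.5))
  expect_equal(got, oracle, tolerance = 1e-10)
  # and the erf-based closed form, up to raster discretisation
  expect_equal(got, pnorm(0.3 / 0.5) - pnorm(-0.3 / 0.5), tolerance = 0.05)

  expect_error(neural_timecourse(pop1, ap1, gains = c(1, 1)), "subunits")
})

test_that("BOLD generation: identity kernel, zero series, noise variance", {
  x <- c(rep(0, 5), 1, 1, rep(0, 13))
  expect_equal(bold_from_neural(x, 1, amplitude = 1, baseline = 0), x)
  set.seed(5)
  y0 <- bold_from_neural(rep(0, 100), hrf_kernel(), baseline = 2,
                         noise_sd = 0.5)
  expect_equal(mean(y0), 2, tolerance = 0.2)
  # Monte-Carlo noise variance
  reps <- replicate(200, bold_from_neural(x, hrf_kernel(), noise_sd = 0.3))
  clean <- bold_from_neural(x, hrf_kernel(), noise_sd = 0)
  # 4000 squared deviations: Monte-Carlo SE of the mean square ~ 2%
  expect_equal(mean((reps - clean)^2), 0.3^2, tolerance = 0.06)
  expect_error(bold_from_neural(x, 1, noise_sd = -1), "noise_sd")
})

test_that("dataset simulation: determinism, A = 0 null, adaptation direction", {
  cfg <- sim_config(n_participants = 1, n_vertices = 25, n_runs = 4,
                    grid_resolution = 0.5)
  d1 <- simulate_fmri_dataset(cfg, seed = 7)
  d2 <- simulate_fmri_dataset(cfg, seed = 7)
  expect_identical(d1, d2)

  # no suppression: truth sigmas identical across conditions
  cfg0 <- sim_config(n_participants = 1, n_vertices = 10, n_runs = 4,
                     adaptation = adaptation_model(amplitude = 0),
                     grid_resolution = 0.5)
  d0 <- simulate_fmri_dataset(cfg0, seed = 7)
  expect_equal(d0$vertices$truth_sigma_high, d0$vertices$truth_sigma_low,
               tolerance = 1e-5)

  # default suppression: high-adapted truth sigma larger, vertex by median
  expect_gt(median(d1$vertices$truth_sigma_high),
            median(d1$vertices$truth_sigma_low))

  expect_error(sim_config(n_runs = 5), "even")
  expect_error(sim_config(noise_rel = -0.1), "noise_rel")
})

test_that("suppression amplitude monotonically widens the truth gap", {
  set.seed(8)
  pop <- sample_population(3, 20, population_config(n_subunits = 30))
  grid <- field_grid(7.5, 0.25)
  gaps <- sapply(c(0, 0.3, 0.6, 0.9), function(A) {
    m <- adaptation_model(amplitude = A)
    abs(effective_sigma_oracle(pop, "high_adapted", grid, m)$sigma -
          effective_sigma_oracle(pop, "low_adapted", grid, m)$sigma)
  })
  expect_true(all(diff(gaps) >= -1e-6))
})

test_that("simulated observer: PSE definition and psychometric shape", {
  obs <- observer_model(noise_sd = 1e-6, lapse = 0)
  set.seed(9)
  # noise -> 0, no shift: ordering is deterministic
  expect_equal(simulate_observer_response(log(1.4), log(1.3), "none", obs),
               "test_higher")
  expect_equal(simulate_observer_response(log(1.2), log(1.3), "none", obs),
               "ref_higher")

  # at test = ref + shift the choice probability is 1/2
  o2 <- observer_model(noise_sd = 0.2, lapse = 0)
  p_half <- mean(replicate(4000, simulate_observer_response(
    log(1.3) + o2$pse_shift[["high_adapt"]], log(1.3), "high_adapt", o2) ==
      "test_higher"))
  expect_equal(p_half, 0.5, tolerance = 0.03)

  # choice proportions trace the cumulative Gaussian
  for (dx in c(-0.3, 0.15)) {
    p <- mean(replicate(3000, simulate_observer_response(
      log(1.3) + dx, log(1.3), "none", o2) == "test_higher"))
    expect_equal(p, pnorm(dx / 0.2), tolerance = 0.035)
  }
  expect_error(observer_model(noise_sd = 0), "positive")
})
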