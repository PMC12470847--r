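# 2D Gaussian pRF estimator: forward model, grid stage, refinement,
# amplitude regression, vertex fitting.

test_that("predict_neural: normalisation, bounds, monotonicity, symmetry", {
  grid <- field_grid(7.5, 0.5)
  npix <- grid$n_pix
  frames <- cbind(rep(0, npix), rep(1, npix))
  ap <- toy_apertures(grid, frames)
  p <- c(x0 = 1, y0 = -2, sigma = 0.8)
  r <- predict_neural(p, ap)
  expect_equal(r, c(0, 1))

  # responses stay in [0, 1] and adding pixels never decreases them
  set.seed(10)
  base <- as.integer(runif(npix) < 0.3)
  grown <- pmax(base, as.integer(runif(npix) < 0.3))
  r2 <- predict_neural(p, toy_apertures(grid, cbind(base, grown)))
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_gte(r2[2], r2[1])

  # centred pRF: a sweep and its 180-degree rotation give time-reversed
  # responses
  ap_run <- fixture("ap_coarse")
  sweep_cols <- function(k) which(grepl(sprintf("^bar\\(%d,", k),
                                        ap_run$annotation))
  resp <- predict_neural(c(x0 = 0, y0 = 0, sigma = 1.5), ap_run)
  expect_equal(resp[sweep_cols(1)], rev(resp[sweep_cols(5)]), tolerance = 1e-9)

  expect_error(predict_neural(c(x0 = 0, y0 = 0, sigma = 0), ap), "sigma")
})

test_that("predict_bold: impulse kernel, zero series, linearity", {
  ap <- fixture("ap_coarse")
  p <- c(x0 = 2, y0 = 1, sigma = 1)
  expect_equal(predict_bold(p, ap, kernel = 1),
               predict_neural(p, ap))
  k <- hrf_kernel()
  y <- predict_bold(p, ap, k)
  expect_equal(length(y), 330)
  expect_equal(predict_bold(p, ap, 2 * k), 2 * y)
  expect_equal(predict_bold(p, ap, k, mapping_only = TRUE),
               y[ap$mapping_idx])
})

test_that("grid stage: self-consistency and brute-force equivalence", {
  ap <- fixture("ap_coarse")
  model <- fixture("model_coarse")
  gp <- fixture("gridpred_coarse")

  # observed generated from a grid member is recovered with r = 1
  theta <- as.numeric(gp$grid[517, ])
  obs <- predict_bold(c(x0 = theta[1], y0 = theta[2], sigma = theta[3]),
                      ap, mapping_only = TRUE)
  got <- grid_stage(obs, gp)
  expect_equal(unname(got$params), theta, tolerance = 1e-9)
  expect_equal(got$cor, 1, tolerance = 1e-9)

  # negated prediction correlates at -1 there, so another cell wins
  gneg <- grid_stage(-obs, gp)
  expect_false(all(unname(gneg$params) == theta))

  # exhaustive brute force over a 100-candidate subgrid equals the
  # operation's output exactly (independent loop oracle)
  sub <- gp$grid[seq(1, nrow(gp$grid), length.out = 100), ]
  gp_sub <- grid_predictions(model, sub)
  set.seed(11)
  obs_n <- obs + rnorm(length(obs), 0, 0.05)
  got_sub <- grid_stage(obs_n, gp_sub)
  brute <- sapply(seq_len(nrow(sub)), function(j) {
    pr <- predict_bold(c(x0 = sub$x0[j], y0 = sub$y0[j], sigma = sub$sigma[j]),
                       ap, mapping_only = TRUE)
    if (sd(pr) < 1e-12) -Inf else cor(obs_n, pr)
  })
  expect_equal(got_sub$index, which.max(brute))
  expect_equal(got_sub$cor, max(brute), tolerance = 1e-9)

  expect_error(grid_stage(rep(1, nrow(gp$P)), gp), "constant")
})

test_that("refinement recovers off-grid parameters and is stationary at truth", {
  ap <- fixture("ap")
  model <- fixture("model")
  gp <- fixture("gridpred")
  truth <- c(x0 = 2.31, y0 = -1.44, sigma = 0.62)
  obs <- predict_bold(truth, ap, mapping_only = TRUE)
  coarse <- grid_stage(obs, gp)
  fine <- refine_stage(obs, model, coarse$params)
  expect_lt(max(abs(fine$params - truth)), 0.05)
  expect_equal(fine$cor, 1, tolerance = 1e-6)
  expect_gte(fine$cor, coarse$cor - 1e-9)

  at_truth <- refine_stage(obs, model, truth)
  expect_lt(max(abs(at_truth$params - truth)), 1e-3)

  # white-noise observed: low correlation, no crash
  set.seed(12)
  noise_fit <- refine_stage(rnorm(length(obs)), model, coarse$params)
  expect_lt(noise_fit$cor, 0.5)

  # objective is invariant to affine transforms of the observed series
  fine2 <- refine_stage(3 * obs + 7, model, coarse$params)
  expect_equal(fine2$params, fine$params, tolerance = 1e-6)
})

test_that("amplitude/baseline regression matches the normal equations", {
  set.seed(13)
  pr <- rnorm(100)
  obs <- 2 * pr + 1
  got <- fit_amplitude_baseline(obs, pr)
  expect_equal(got$beta, 2)
  expect_equal(got$baseline, 1)
  expect_equal(got$r2, 1)

  # orthogonal observed: beta ~ 0, r2 ~ 0
  prc <- pr - mean(pr)
  orth <- rnorm(100)
  orth <- orth - mean(orth)
  orth <- orth - prc * sum(orth * prc) / sum(prc^2)
  g2 <- fit_amplitude_baseline(orth, pr)
  expect_lt(abs(g2$beta), 1e-10)
  expect_lt(g2$r2, 1e-10)

  # random case against closed-form OLS (independent oracle)
  o <- rnorm(60); pr2 <- rnorm(60)
  X <- cbind(1, pr2)
  co <- solve(t(X) %*% X, t(X) %*% o)
  g3 <- fit_amplitude_baseline(o, pr2)
  expect_equal(g3$baseline, co[1])
  expect_equal(g3$beta, co[2])
  expect_equal(g3$r2, cor(o, pr2)^2)

  expect_error(fit_amplitude_baseline(o, rep(2, 60)), "constant")
})

test_that("fit_vertex: stateless, robust to out-of-aperture truth", {
  ap <- fixture("ap")
  model <- fixture("model")
  gp <- fixture("gridpred")
  obs <- predict_bold(c(x0 = -3, y0 = 2, sigma = 1.1), ap,
                      mapping_only = TRUE)
  f1 <- fit_vertex(obs, model, gp)
  f2 <- fit_vertex(obs, model, gp)
  expect_identical(f1, f2)  # no hidden state
  expect_equal(f1$ecc, sqrt(f1$x0^2 + f1$y0^2))
  expect_equal(f1$polar, atan2(f1$y0, f1$x0))
  expect_equal(f1$r2, 1, tolerance = 1e-6)

  # truth outside the aperture: poor/boundary fit, flagged or low r2 is
  # acceptable, crashing is not
  far <- predict_bold(c(x0 = 10, y0 = 0, sigma = 0.4), ap,
                      mapping_only = TRUE)
  expect_no_error(ffar <- fit_vertex(far, model, gp))
  expect_true(ffar$flag %in% c("ok", "refine_failed", "fit_failed"))

  # full-run input is cropped to the mapping volumes internally
  obs_full <- predict_bold(c(x0 = -3, y0 = 2, sigma = 1.1), ap)
  expect_equal(fit_vertex(obs_full, model, gp)$sigma, f1$sigma,
               tolerance = 1e-6)
})

test_that("noise robustness: sigma bias small at split-half r ~ 0.7", {
  # compact version of the recovery suite (the acceptance suite runs the
  # full 200-vertex version)
  ap <- fixture("ap"); model <- fixture("model"); gp <- fixture("gridpred")
  set.seed(14)
  pos <- draw_stim_position(40, c(0.5, 7))
  sig <- runif(40, 0.3, 2)
  est <- shr <- numeric(40)
  for (i in 1:40) {
    clean <- predict_bold(c(x0 = pos$x0[i], y0 = pos$y0[i], sigma = sig[i]), ap)
    runs <- clean + matrix(rnorm(330 * 4, 0, 0.93 * sd(clean)), 330, 4)
    pre <- apply(runs, 2, detrend_zscore)
    shr[i] <- split_half_reliability(pre)
    est[i] <- fit_vertex(average_runs(pre), model, gp)$sigma
  }
  expect_equal(median(shr), 0.7, tolerance = 0.1)
  expect_lt(abs(mean(est) - mean(sig)) / mean(sig), 0.1)
})
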