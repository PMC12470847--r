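# Staircases, psychometric fitting, reversal-based PSEs and the
# behavioural analysis chain.

test_that("staircase mechanics: stepping, snapping, reversal halving, floor", {
  s <- staircase_new(start_level = 3.8, ref_level = geometric_mean_sf(0.5, 3.5))
  expect_equal(s$level, 3.8)
  s <- staircase_update(s, "down")   # "test higher" response
  expect_equal(s$level, 3.3, tolerance = 0.01)  # 3.8 - 0.5, snapped
  expect_equal(s$step, 0.5)          # no reversal yet

  s <- staircase_update(s, "down")
  s <- staircase_update(s, "up")     # first reversal
  expect_equal(s$step, 0.25)
  expect_equal(length(s$reversals), 1)
  s <- staircase_update(s, "down")   # second reversal
  expect_equal(s$step, 0.125)
  # step never goes below the floor
  for (i in 1:6) s <- staircase_update(s, c("up", "down")[i %% 2 + 1])
  expect_equal(s$step, 0.125)
  expect_equal(max(0.5 / 2^5, 0.125), 0.125)

  # levels stay inside the 30-level set: many "up" steps clamp at the top
  s2 <- staircase_new(start_level = 0.2)
  for (i in 1:29) s2 <- staircase_update(s2, "up")
  expect_equal(s2$level, 3.8)
  expect_true(min(abs(s2$level - sf_test_levels())) < 1e-9)
  s3 <- staircase_new(n_trials = 2)
  s3 <- staircase_update(staircase_update(s3, "up"), "up")
  expect_true(s3$terminated)
  expect_error(staircase_update(s3, "up"), "terminated")
})

test_that("staircase converges to the observer's 50% point", {
  set.seed(40)
  obs <- observer_model(noise_sd = 0.18, lapse = 0)
  ref <- geometric_mean_sf(0.5, 3.5)
  target <- log(ref) + obs$pse_shift[["low_adapt"]]
  s <- staircase_new(start_level = 3.8, n_trials = 1000)
  while (!s$terminated) {
    resp <- simulate_observer_response(log(s$level), log(ref), "low_adapt", obs)
    s <- staircase_update(s, if (resp == "test_higher") "down" else "up")
  }
  late <- s$reversals[-seq_len(10)]
  expect_equal(mean(log(late)), target, tolerance = 0.05)
})

test_that("session structure: block order, counts, determinism", {
  set.seed(41)
  tr <- run_session(observer_model(), session = 1, participant = 1)
  expect_equal(nrow(tr), 360)  # 6 blocks x 2 staircases x 30 trials
  expect_equal(sort(unique(tr$condition)),
               c("high_adapt", "low_adapt", "none"))
  # the first 120 trials are the two no-adaptation blocks
  expect_true(all(tr$condition[1:120] == "none"))
  expect_equal(sort(unique(tr$side[1:120])), c("left", "right"))
  # each staircase runs exactly 30 trials
  expect_true(all(table(tr$condition, tr$side, tr$staircase) %in% c(0, 30)))
  # all levels live on the discrete set
  expect_true(all(sapply(tr$test_level, function(l)
    min(abs(l - sf_test_levels()))) < 1e-9))

  t1 <- simulate_behaviour_experiment(2, 1, seed = 5)
  t2 <- simulate_behaviour_experiment(2, 1, seed = 5)
  expect_identical(t1, t2)
})

test_that("psychometric fit: recovery, limiting step, exchangeability, failures", {
  set.seed(42)
  # recovery of a known generating function
  mu <- log(1.5); sdev <- 0.2
  lv <- sf_test_levels()
  x <- log(sample(lv, 1500, replace = TRUE))
  p <- pnorm((x - mu) / sdev)
  tr <- data.frame(test_level = exp(x),
                   response = ifelse(runif(1500) < p, "test_higher",
                                     "ref_higher"))
  fit <- fit_psychometric(tr)
  expect_lt(abs(fit$pse - mu), 0.03)
  expect_equal(1 / fit$slope, sdev, tolerance = 0.1)
  expect_true(fit$pse >= fit$pse_ci[1] && fit$pse <= fit$pse_ci[2])

  # hard step at level L: PSE -> log L
  L <- 1.54
  tr_step <- data.frame(test_level = rep(lv, each = 8),
                        response = ifelse(rep(lv, each = 8) > L,
                                          "test_higher", "ref_higher"))
  expect_equal(fit_psychometric(tr_step)$pse, log(L), tolerance = 0.07)

  # refitting with trials in a different order gives the identical fit
  perm <- sample(nrow(tr))
  fit2 <- fit_psychometric(tr[perm, ])
  expect_equal(fit2$pse, fit$pse)
  expect_equal(fit2$slope, fit$slope)

  expect_error(fit_psychometric(data.frame(test_level = c(1, 2),
                                           response = c("test_higher",
                                                        "test_higher"))),
               "one way")
  expect_error(fit_psychometric(data.frame(test_level = 1,
                                           response = "test_higher")),
               "distinct")
})

test_that("bias correction and aftereffect percentages", {
  expect_equal(bias_correct(0.3, 0.3), 0)
  expect_equal(bias_correct(0.1 + log(1.07), 0.1), log(1.07))
  expect_equal(aftereffect_percent(0), 0)
  expect_equal(aftereffect_percent(log(1.07)), 7)
  expect_equal(aftereffect_percent(log(0.87)), -13)
  # invariance to a common additive offset on both PSEs
  for (off in c(-0.4, 0.25))
    expect_equal(aftereffect_percent(bias_correct(0.2 + off, 0.05 + off)),
                 aftereffect_percent(bias_correct(0.2, 0.05)))
})

test_that("reversal-based PSE: drop rule, MAD exclusion, permutation invariance", {
  expect_equal(reversal_pse(rep(0.4, 5))$estimate, 0.4)
  r3 <- reversal_pse(c(0.5, 0.4, 0.45))
  expect_true(r3$rejected)
  expect_equal(r3$reason, "insufficient_reversals")

  # one extreme value is excluded by the +-2 MAD rule (hand oracle)
  revs <- c(0.9, 0.8, 0.85, 0.52, 0.50, 0.55, 0.54, 0.95, 0.53)
  rest <- revs[-(1:3)]
  med <- median(rest); madu <- median(abs(rest - med))
  keep <- abs(rest - med) <= 2 * madu
  got <- reversal_pse(revs)
  expect_equal(got$estimate, mean(rest[keep]))
  expect_lt(got$estimate, 0.6)   # the 0.95 outlier is gone
  expect_equal(got$n_used, sum(keep))

  # invariant to permutation of the post-drop reversals
  perm <- c(revs[1:3], sample(rest))
  expect_equal(reversal_pse(perm)$estimate, got$estimate)
})

test_that("behavioural analysis recovers generating shifts (compact)", {
  tr <- simulate_behaviour_experiment(4, 2, seed = 10)
  res <- analyze_behaviour(tr)
  g <- res$group[res$group$family == "raw", ]
  expect_equal(g$mean_pct[g$condition == "low_adapt"], 7, tolerance = 3)
  expect_equal(g$mean_pct[g$condition == "high_adapt"], -13, tolerance = 3)
  expect_equal(g$mean_pct[g$condition == "none"], 0, tolerance = 2.5)
  # per-participant table carries both sides and corrected shifts
  expect_equal(nrow(res$participants), 4 * 3)
  expect_true(all(is.na(
    res$participants$corrected_shift[res$participants$condition == "none"])))
})

test_that("contrast control chain counts rejections and pools log PSEs", {
  trc <- simulate_behaviour_experiment(
    3, 2, seed = 11,
    observer = observer_model(pse_shift = c(low_adapt = -0.1,
                                            high_adapt = -0.1, none = 0),
                              noise_sd = 0.12),
    task = "contrast")
  expect_true(all(sapply(trc$test_level, function(l)
    min(abs(l - contrast_levels()))) < 1e-9))
  rc <- analyze_contrast(trc)
  expect_equal(nrow(rc$measurements), 3 * 2 * 6 * 2)
  expect_true(all(c("participant", "condition", "mean_log_pse") %in%
                    names(rc$participants)))
  expect_equal(rc$n_rejected, sum(rc$measurements$rejected))
})
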