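# Behavioural arm: interleaved 1-up-1-down staircases over a discrete
# level set, log-normal (cumulative Gaussian in log SF) psychometric fits
# with the PSE at the half-proportion point, bias correction, aftereffect
# percentages, and the reversal-based PSE with MAD outlier rejection used
# for the contrast control task.

#' Test stimulus level sets
#'
#' The SF task uses 30 test SFs evenly spaced over 0.2--3.8 cpd (spacing
#' 3.6/29 ~ 0.124 cpd, matching the terminal staircase step); the contrast
#' control task uses 30 contrasts from 0.01 in steps of 0.031 with the
#' last level clamped to the reference contrast 1.0 (the printed endpoints
#' and step are mutually inconsistent; the clamp resolves this in favour
#' of testing the full range).
#'
#' @return numeric vector of 30 levels.
#' @export
sf_test_levels <- function() seq(0.2, 3.8, length.out = 30)

#' @rdname sf_test_levels
#' @export
contrast_levels <- function() {
  lv <- 0.01 + (0:29) * 0.031
  lv[30] <- 1.0
  lv
}

# Snap to the nearest available level; exact ties resolved toward the
# reference.
snap_level <- function(value, levels, ref) {
  d <- abs(levels - value)
  cand <- which(d < min(d) + 1e-12)
  if (length(cand) > 1) cand <- cand[which.min(abs(levels[cand] - ref))]
  levels[cand]
}

#' Create a 1-up-1-down staircase
#'
#' @param levels discrete level set the staircase moves on.
#' @param start_level starting level (snapped into the set).
#' @param step_init initial step size (same units as levels).
#' @param step_floor smallest step; the step is halved at every response
#'   reversal until it reaches this floor.
#' @param n_trials trials before termination.
#' @param ref_level reference level used only for snap tie-breaking.
#' @return object of class `staircase`.
#' @export
staircase_new <- function(levels = sf_test_levels(), start_level = 3.8,
                          step_init = 0.5, step_floor = 0.125,
                          n_trials = 30, ref_level = mean(range(levels))) {
  stopifnot(step_init > 0, step_floor > 0, n_trials >= 1)
  structure(list(
    levels = sort(levels),
    level = snap_level(start_level, levels, ref_level),
    step = step_init, step_floor = step_floor,
    last_direction = NA_integer_, trial_count = 0L,
    reversals = numeric(0), n_trials = n_trials,
    ref_level = ref_level, terminated = FALSE,
    last_was_reversal = FALSE
  ), class = "staircase")
}

#' Advance a staircase by one response
#'
#' One-up one-down: the level moves one step against the response
#' (`"down"` after the signal that the test exceeded the reference,
#' `"up"` otherwise). On a direction reversal the level at which it
#' occurred is recorded and the step is halved, never below the floor.
#' The new level is snapped to the nearest member of the level set (which
#' also clamps it to the set boundaries). The staircase terminates after
#' `n_trials` responses.
#'
#' @param state a [staircase_new()].
#' @param signal `"up"` or `"down"`.
#' @return updated state; `state$last_was_reversal` flags whether this
#'   response produced a reversal.
#' @export
staircase_update <- function(state, signal = c("down", "up")) {
  if (state$terminated) stop("staircase already terminated")
  signal <- match.arg(signal)
  direction <- if (signal == "up") 1L else -1L
  reversal <- !is.na(state$last_direction) &&
    direction != state$last_direction
  if (reversal) {
    state$reversals <- c(state$reversals, state$level)
    state$step <- max(state$step / 2, state$step_floor)
  }
  state$last_was_reversal <- reversal
  state$level <- snap_level(state$level + direction * state$step,
                            state$levels, state$ref_level)
  state$last_direction <- direction
  state$trial_count <- state$trial_count + 1L
  state$terminated <- state$trial_count >= state$n_trials
  state
}

# One block: two interleaved staircases (high and low start), interleaving
# order random among non-terminated staircases.
run_block <- function(observer, condition, side, session, participant,
                      task = c("sf", "contrast"),
                      ref_level = geometric_mean_sf(0.5, 3.5)) {
  task <- match.arg(task)
  if (task == "sf") {
    levels <- sf_test_levels()
    stairs <- list(staircase_new(levels, 3.8, 0.5, 0.125, ref_level = ref_level),
                   staircase_new(levels, 0.2, 0.5, 0.125, ref_level = ref_level))
  } else {
    levels <- contrast_levels()
    stairs <- list(staircase_new(levels, 1.0, 0.124, 0.031, ref_level = ref_level),
                   staircase_new(levels, 0.1, 0.124, 0.031, ref_level = ref_level))
  }
  n_total <- sum(vapply(stairs, function(s) as.integer(s$n_trials), 1L))
  rec <- vector("list", n_total)
  for (t in seq_len(n_total)) {
    active <- which(!vapply(stairs, function(s) s$terminated, TRUE))
    sc <- if (length(active) == 1) active else sample(active, 1)
    lev <- stairs[[sc]]$level
    resp <- simulate_observer_response(log(lev), log(ref_level),
                                       condition, observer)
    signal <- if (resp == "test_higher") "down" else "up"
    stairs[[sc]] <- staircase_update(stairs[[sc]], signal)
    rec[[t]] <- data.frame(
      participant = participant, session = session, condition = condition,
      side = side, staircase = sc, trial = stairs[[sc]]$trial_count,
      test_level = lev, ref_level = ref_level, response = resp,
      reversal = stairs[[sc]]$last_was_reversal,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rec)
}

#' Simulate one experimental session
#'
#' Six blocks: three adaptation conditions (none, low adapt, high adapt)
#' crossed with two adapted sides; the two no-adaptation blocks always
#' come first (guarding against carry-over of adaptation), the remaining
#' four in random order. Each block interleaves two 30-trial staircases
#' starting from the extremes of the level set.
#'
#' @param observer an [observer_model()].
#' @param session session number recorded in the trial table.
#' @param participant participant id recorded in the trial table.
#' @param task `"sf"` (default) or `"contrast"`.
#' @return trial table (one row per trial).
#' @export
run_session <- function(observer, session = 1, participant = 1,
                        task = c("sf", "contrast")) {
  task <- match.arg(task)
  ref <- if (task == "sf") geometric_mean_sf(0.5, 3.5) else 1.0
  first <- data.frame(condition = "none", side = sample(c("left", "right")),
                      stringsAsFactors = FALSE)
  rest <- expand.grid(condition = c("low_adapt", "high_adapt"),
                      side = c("left", "right"), stringsAsFactors = FALSE)
  rest <- rest[sample(nrow(rest)), ]
  blocks <- rbind(first, rest)
  do.call(rbind, lapply(seq_len(nrow(blocks)), function(i)
    run_block(observer, blocks$condition[i], blocks$side[i], session,
              participant, task, ref)))
}

#' Simulate the full behavioural experiment
#'
#' @param n_participants,n_sessions experiment size (10 participants, 2-4
#'   sessions each in the emulated design; 3 by default).
#' @param observer an [observer_model()] shared by all participants, or a
#'   list of per-participant models.
#' @param seed integer seed.
#' @param task `"sf"` or `"contrast"`.
#' @return trial table across participants and sessions.
#' @export
simulate_behaviour_experiment <- function(n_participants = 10,
                                          n_sessions = 3,
                                          observer = observer_model(),
                                          seed = 1,
                                          task = c("sf", "contrast")) {
  task <- match.arg(task)
  set.seed(stage_seed(seed, paste0("psychophysics-", task)))
  obs_for <- function(p)
    if (inherits(observer, "observer_model")) observer else observer[[p]]
  do.call(rbind, lapply(seq_len(n_participants), function(p)
    do.call(rbind, lapply(seq_len(n_sessions), function(s)
      run_session(obs_for(p), session = s, participant = p, task = task)))))
}

#' Maximum-likelihood psychometric fit in log SF
#'
#' Cumulative Gaussian in log stimulus level with a symmetric guess/lapse
#' rate bounded at 0.05:
#' `P(test judged higher) = lambda + (1 - 2 lambda) * Phi((x - pse) / s)`.
#' Because the lapse is symmetric the fitted function passes 0.5 exactly
#' at `x = pse`, so the PSE is the half-proportion point. A cumulative
#' Gaussian in log SF is a log-normal function of SF.
#'
#' @param trials data frame with `test_level` (linear units, e.g. cpd) and
#'   `response` (`"test_higher"` / `"ref_higher"`).
#' @return object of class `psychometric_fit`: `pse` (log units), `slope`
#'   (`1/s`), `lapse`, `loglik`, `pse_se`, `pse_ci` (Wald 95%), `n_trials`.
#' @export
fit_psychometric <- function(trials) {
  x <- log(trials$test_level)
  k <- as.integer(trials$response == "test_higher")
  if (length(unique(x)) < 2)
    stop("need responses at >= 2 distinct levels")
  if (all(k == 1) || all(k == 0))
    stop("responses do not bracket the PSE (all one way)")
  agg <- aggregate(cbind(n = rep(1, length(k)), k = k), by = list(x = x), sum)
  nll <- function(par) {
    pse <- par[1]; s <- exp(par[2]); lam <- par[3]
    p <- lam + (1 - 2 * lam) * pnorm((agg$x - pse) / s)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
  }
  # crude init: level closest to 50% responding, spread from the data range
  phat <- agg$k / agg$n
  init <- c(agg$x[which.min(abs(phat - 0.5))], log(diff(range(agg$x)) / 4),
            0.01)
  fit <- optim(init, nll, method = "L-BFGS-B",
               lower = c(min(agg$x) - 2, log(1e-3), 0),
               upper = c(max(agg$x) + 2, log(5), 0.05),
               hessian = TRUE)
  se <- tryCatch({
    v <- solve(fit$hessian)[1, 1]
    if (is.finite(v) && v > 0) sqrt(v) else NA_real_
  }, error = function(e) NA_real_)
  structure(list(pse = fit$par[1], slope = 1 / exp(fit$par[2]),
                 lapse = fit$par[3], loglik = -fit$value,
                 pse_se = se,
                 pse_ci = fit$par[1] + c(-1.96, 1.96) * se,
                 n_trials = sum(agg$n)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> PSE = %.4f log units (%.3f cpd), slope = %.2f, lapse = %.3f, n = %d\n",
    x$pse, exp(x$pse), x$slope, x$lapse, x$n_trials))
  invisible(x)
}

#' Response-bias correction of a PSE
#'
#' @param pse_adapt,pse_none PSEs in log units from the same adapted side.
#' @return bias-corrected shift in log units.
#' @export
bias_correct <- function(pse_adapt, pse_none) {
  stopifnot(is.finite(pse_adapt), is.finite(pse_none))
  pse_adapt - pse_none
}

#' Aftereffect as a percentage change in perceived SF
#'
#' @param shift log-unit shift.
#' @return `(exp(shift) - 1) * 100`, e.g. `log(1.07)` -> +7%.
#' @export
aftereffect_percent <- function(shift) (exp(shift) - 1) * 100

#' Reversal-based PSE of one staircase
#'
#' Drops the first three reversals, excludes remaining reversal levels
#' more than 2 (unscaled) median absolute deviations from their median,
#' and returns the mean of the survivors. Staircases with three or fewer
#' reversals are rejected, as are those whose reversals are all excluded.
#'
#' @param reversals reversal levels in presentation order.
#' @param drop_first reversals discarded from the start.
#' @param mad_mult exclusion threshold in MADs.
#' @return list: `estimate` (NA when rejected), `rejected`, `reason`
#'   (`"ok"`, `"insufficient_reversals"`, `"all_excluded"`), `n_used`.
#' @export
reversal_pse <- function(reversals, drop_first = 3, mad_mult = 2) {
  if (length(reversals) <= drop_first)
    return(list(estimate = NA_real_, rejected = TRUE,
                reason = "insufficient_reversals", n_used = 0L))
  rest <- reversals[-seq_len(drop_first)]
  med <- median(rest)
  mad_u <- median(abs(rest - med))  # unscaled MAD
  keep <- abs(rest - med) <= mad_mult * mad_u
  if (!any(keep))
    return(list(estimate = NA_real_, rejected = TRUE,
                reason = "all_excluded", n_used = 0L))
  list(estimate = mean(rest[keep]), rejected = FALSE, reason = "ok",
       n_used = sum(keep))
}

#' Full behavioural analysis: PSEs, shifts, aftereffects, group tests
#'
#' SF task: per participant, condition and adapted side, trials are pooled
#' across sessions and fitted psychometrically; adaptation PSEs are bias
#' corrected by the same-side no-adaptation PSE, then the two sides are
#' averaged. Group inference is by one-sample t-tests on the log shifts
#' (raw shifts relative to the veridical reference for all three
#' conditions, Bonferroni x3; bias-corrected shifts for the two adaptation
#' conditions, Bonferroni x2).
#'
#' @param trials table from [simulate_behaviour_experiment()] (sf task).
#' @return list: `participants` (per participant x condition: pse per
#'   side, shift, aftereffect %), `group` (per condition: mean %, t, df,
#'   p, p_bonf for raw and bias-corrected families).
#' @export
analyze_behaviour <- function(trials) {
  stopifnot(nrow(trials) > 0)
  ref_log <- log(trials$ref_level[1])
  conds <- c("none", "low_adapt", "high_adapt")
  prows <- list()
  for (p in unique(trials$participant)) {
    tp <- trials[trials$participant == p, ]
    pse <- sapply(conds, function(cn) sapply(c("left", "right"), function(sd)
      fit_psychometric(tp[tp$condition == cn & tp$side == sd, ])$pse))
    # pse is side x condition
    for (cn in conds) {
      raw_shift <- mean(pse[, cn]) - ref_log
      corr_shift <- if (cn == "none") NA_real_ else
        mean(bias_correct(pse[, cn], pse[, "none"]))
      prows[[length(prows) + 1]] <- data.frame(
        participant = p, condition = cn,
        pse_left = pse["left", cn], pse_right = pse["right", cn],
        raw_shift = raw_shift, corrected_shift = corr_shift,
        raw_pct = aftereffect_percent(raw_shift),
        corrected_pct = aftereffect_percent(corr_shift),
        stringsAsFactors = FALSE)
    }
  }
  participants <- do.call(rbind, prows)
  one_sample <- function(x, m) {
    tt <- stats::t.test(x)
    data.frame(mean_pct = mean(aftereffect_percent(x)), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               p_bonf = min(1, tt$p.value * m))
  }
  group <- do.call(rbind, lapply(conds, function(cn) {
    px <- participants[participants$condition == cn, ]
    raw <- one_sample(px$raw_shift, 3)
    out <- cbind(data.frame(condition = cn, family = "raw"), raw)
    if (cn != "none") {
      corr <- one_sample(px$corrected_shift, 2)
      out <- rbind(out, cbind(data.frame(condition = cn,
                                         family = "bias_corrected"), corr))
    }
    out
  }))
  rownames(group) <- NULL
  list(participants = participants, group = group)
}

#' Reversal-based analysis of the contrast control task
#'
#' Each measurement (participant x session x condition x side x staircase)
#' yields a reversal-based PSE; log PSEs of repeated measurements of the
#' same condition are averaged per participant after bias correction is
#' applied on the log scale. Participants for whom any condition has no
#' usable staircase are dropped (mirroring the rejection rule).
#'
#' @param trials table from `simulate_behaviour_experiment(task = "contrast")`.
#' @return list: `measurements` (per staircase: estimate, rejected),
#'   `participants` (per participant x condition: mean log PSE),
#'   `n_rejected` staircases.
#' @export
analyze_contrast <- function(trials) {
  key <- interaction(trials$participant, trials$session, trials$condition,
                     trials$side, trials$staircase, drop = TRUE)
  meas <- lapply(split(trials, key), function(g) {
    rp <- reversal_pse(g$test_level[g$reversal])
    data.frame(participant = g$participant[1], session = g$session[1],
               condition = g$condition[1], side = g$side[1],
               staircase = g$staircase[1], estimate = rp$estimate,
               rejected = rp$rejected, stringsAsFactors = FALSE)
  })
  meas <- do.call(rbind, meas)
  rownames(meas) <- NULL
  ok <- meas[!meas$rejected, ]
  parts <- aggregate(log(ok$estimate),
                     by = list(participant = ok$participant,
                               condition = ok$condition),
                     FUN = mean)
  names(parts)[3] <- "mean_log_pse"
  list(measurements = meas, participants = parts,
       n_rejected = sum(meas$rejected))
}
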