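# Pre-fit conditioning and post-fit quality control: detrend/z-score,
# run averaging, split-half noise ceiling, nR^2, and the four
# vertex-exclusion rules.

#' Linear detrend then z-score a run
#'
#' @param x series of length >= 3, nonconstant after detrending.
#' @return series with the OLS linear trend removed, mean 0 and SD 1.
#' @export
detrend_zscore <- function(x) {
  n <- length(x)
  if (n < 3) stop("series too short")
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc^2)
  r <- x - mean(x) - slope * tc
  s <- sd(r)
  if (!is.finite(s) || s < 1e-12)
    stop("series is constant after detrending")
  r / s
}

#' Pointwise mean of preprocessed runs
#'
#' @param runs time x run matrix of detrended/z-scored runs.
#' @return averaged series.
#' @export
average_runs <- function(runs) {
  runs <- as.matrix(runs)
  if (ncol(runs) < 1) stop("need at least one run")
  rowMeans(runs)
}

#' Odd/even split-half reliability
#'
#' Pearson correlation between the mean of odd-indexed and the mean of
#' even-indexed runs of one condition.
#'
#' @param runs time x run matrix (>= 2 runs).
#' @return correlation in `[-1, 1]`.
#' @export
split_half_reliability <- function(runs) {
  runs <- as.matrix(runs)
  if (ncol(runs) < 2) stop("need at least two runs")
  odd <- rowMeans(runs[, seq(1, ncol(runs), by = 2), drop = FALSE])
  even <- rowMeans(runs[, seq(2, ncol(runs), by = 2), drop = FALSE])
  if (sd(odd) < 1e-12 || sd(even) < 1e-12) stop("constant half series")
  cor(odd, even)
}

#' Spearman-Brown prophecy formula
#'
#' Reliability of the lengthened measurement: `k r / (1 + (k - 1) r)`,
#' clamped to 0 for non-positive split-half correlations (an unreliable
#' response cannot bound goodness of fit). With the default `k = 2` this
#' steps up from the two half-session averages to the full session, and is
#' the noise ceiling used to normalise R^2.
#'
#' @param r split-half correlation.
#' @param k lengthening factor.
#' @return reliability in `[0, 1]` for `r <= 1`.
#' @export
spearman_brown <- function(r, k = 2) {
  out <- ifelse(r <= 0, 0, k * r / (1 + (k - 1) * r))
  out
}

#' Noise-ceiling-normalised goodness of fit
#'
#' @param r2 model R^2 in `[0, 1]`.
#' @param ceiling noise ceiling; a zero ceiling yields `nr2 = 0` (the
#'   vertex is then excluded by the nR^2 threshold).
#' @return nR^2 = r2 / ceiling.
#' @export
normalized_r2 <- function(r2, ceiling) {
  ifelse(ceiling <= 0, 0, r2 / ceiling)
}

#' Vertex exclusion rules
#'
#' A vertex is kept iff `sigma > 0`, not (`x0 == 0` and `y0 == 0`),
#' `0.01 <= beta <= 3`, and `nr2 >= 0.2` (boundary values kept: the
#' exclusions are strict inequalities). `reason` records the first
#' violated rule in the order sigma, origin, beta, nr2.
#'
#' @param fits data frame with columns `sigma`, `x0`, `y0`, `beta`, `nr2`.
#' @return `fits` with added logical `keep` and character `reason`
#'   (`"pass"` for kept rows). Filtering is idempotent and
#'   order-independent.
#' @export
filter_vertices <- function(fits) {
  need <- c("sigma", "x0", "y0", "beta", "nr2")
  if (!all(need %in% names(fits)))
    stop("missing columns: ", paste(setdiff(need, names(fits)), collapse = ", "))
  reason <- rep("pass", nrow(fits))
  bad_nr2 <- fits$nr2 < 0.2
  reason[bad_nr2] <- "nr2"
  bad_beta <- fits$beta < 0.01 | fits$beta > 3
  reason[bad_beta] <- "beta"
  bad_origin <- fits$x0 == 0 & fits$y0 == 0
  reason[bad_origin] <- "origin"
  bad_sigma <- fits$sigma <= 0
  reason[bad_sigma] <- "sigma"
  fits$keep <- reason == "pass"
  fits$reason <- reason
  fits
}
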