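# Group statistics: Mood's median tests, difference and proportional-change
# measures, sliding eccentricity bins, repeated-measures ANOVA with
# Greenhouse-Geisser correction, and the per-participant summary with FDR.

#' Mood's median test for two independent samples
#'
#' Counts observations above the pooled median per group and tests the
#' 2 x 2 table with the Pearson chi-square (df = 1, no continuity
#' correction). Ties at the pooled median count as "not above". The
#' statistic depends on the data only through ranks relative to the pooled
#' median, so it is invariant under strictly monotone transforms.
#'
#' @param a,b numeric samples.
#' @return list of class `moods_median_test`: `pooled_median`, `table`
#'   (2 x 2 counts), `chi2`, `df`, `p`, `degenerate` (TRUE when a table
#'   margin is empty, in which case `chi2 = 0`, `p = 1` by convention).
#' @export
moods_median_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  m <- median(c(a, b))
  tab <- rbind(a = c(above = sum(a > m), not_above = sum(a <= m)),
               b = c(above = sum(b > m), not_above = sum(b <= m)))
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    return(structure(list(pooled_median = m, table = tab, chi2 = 0,
                          df = 1L, p = 1, degenerate = TRUE),
                     class = "moods_median_test"))
  }
  chi2 <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(c(rs, cs))
  structure(list(pooled_median = m, table = tab, chi2 = chi2, df = 1L,
                 p = pchisq(chi2, 1, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "moods_median_test")
}

#' @export
print.moods_median_test <- function(x, ...) {
  cat(sprintf("Mood's median test: chi2(1) = %.3f, p = %.4g (pooled median %.3g)\n",
              x$chi2, x$p, x$pooled_median))
  invisible(x)
}

#' Per-vertex pRF size difference between conditions
#'
#' `diff = sigma_high - sigma_low` for vertices present in both condition
#' tables, with the across-condition mean eccentricity attached for
#' binning (averaging mitigates, without removing, regression-to-the-mean
#' binning bias).
#'
#' @param fits_high,fits_low data frames with `vertex_id`, `sigma`, `ecc`
#'   (e.g. QC-passed rows of [fit_dataset()] output split by condition).
#' @return data frame `vertex_id`, `sigma_high`, `sigma_low`, `diff`,
#'   `ecc` (mean of the two conditions).
#' @export
size_difference <- function(fits_high, fits_low) {
  ids <- intersect(fits_high$vertex_id, fits_low$vertex_id)
  if (length(ids) == 0) stop("no shared vertices between conditions")
  h <- fits_high[match(ids, fits_high$vertex_id), ]
  l <- fits_low[match(ids, fits_low$vertex_id), ]
  data.frame(vertex_id = ids,
             sigma_high = h$sigma, sigma_low = l$sigma,
             diff = h$sigma - l$sigma,
             ecc = (h$ecc + l$ecc) / 2)
}

#' Proportional pRF size difference
#'
#' Symmetric percent difference `(sigma_high - sigma_low) / mean(sigmas)`,
#' antisymmetric under swapping the conditions; makes size changes
#' comparable across visual areas with very different baseline pRF sizes.
#'
#' @param sigma_high,sigma_low positive sizes, deg.
#' @return unitless proportional difference.
#' @export
proportional_difference <- function(sigma_high, sigma_low) {
  if (any(sigma_high <= 0) || any(sigma_low <= 0))
    stop("sizes must be positive")
  (sigma_high - sigma_low) / ((sigma_high + sigma_low) / 2)
}

#' Sliding eccentricity bins of a per-vertex quantity
#'
#' 100 overlapping 1-degree-wide bins with centres evenly spaced over
#' `[range[1] + width/2, range[2] - width/2]`; bin b collects vertices
#' with eccentricity in `[centre - width/2, centre + width/2)` and
#' reports their median; bins with fewer than `min_count` vertices are
#' returned as `NA`.
#'
#' @param ecc,value equal-length vectors.
#' @param n_bins,width,range,min_count binning parameters.
#' @return data frame `centre`, `median`, `n`.
#' @export
sliding_bins <- function(ecc, value, n_bins = 100, width = 1,
                         range = c(0, 8), min_count = 10) {
  if (length(ecc) != length(value)) stop("ecc and value length mismatch")
  if (length(ecc) == 0) stop("empty input")
  centres <- seq(range[1] + width / 2, range[2] - width / 2,
                 length.out = n_bins)
  med <- n <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    inb <- ecc >= centres[b] - width / 2 & ecc < centres[b] + width / 2
    n[b] <- sum(inb)
    med[b] <- if (n[b] >= min_count) median(value[inb]) else NA_real_
  }
  data.frame(centre = centres, median = med, n = n)
}

#' Across-participant mean profile of binned medians
#'
#' @param profiles list of per-participant [sliding_bins()] outputs on the
#'   same bin centres.
#' @return data frame `centre`, `mean`, `sem` (between-participant SEM),
#'   `n_participants` per bin.
#' @export
group_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  M <- sapply(profiles, function(p) p$median)
  if (is.null(dim(M))) M <- matrix(M, ncol = length(profiles))
  n_p <- rowSums(!is.na(M))
  mu <- rowMeans(M, na.rm = TRUE)
  s <- apply(M, 1, sd, na.rm = TRUE)
  data.frame(centre = profiles[[1]]$centre,
             mean = ifelse(n_p > 0, mu, NA_real_),
             sem = ifelse(n_p > 1, s / sqrt(n_p), NA_real_),
             n_participants = n_p)
}

# Orthonormal basis of the contrast space of a k-level factor.
orthonormal_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Both factors within-subject, complete balanced data. Each effect is
#' tested through its orthonormal contrast scores; the Greenhouse-Geisser
#' epsilon is estimated from the covariance of those scores and applied to
#' effects with more than 1 numerator df (a 2-level factor has epsilon 1
#' by construction).
#'
#' @param data data frame with subject, two factor columns and a value
#'   column.
#' @param subject,factor_a,factor_b,value column names.
#' @return data frame, one row per effect (`A`, `B`, `A:B`): `F`, `df1`,
#'   `df2`, `p` (uncorrected), `epsilon`, `df1_gg`, `df2_gg`, `p_gg`.
#' @export
rm_anova_2way <- function(data, subject = "participant", factor_a = "roi",
                          factor_b = "condition", value = "value") {
  f_s <- factor(data[[subject]])
  f_a <- factor(data[[factor_a]])
  f_b <- factor(data[[factor_b]])
  a <- nlevels(f_a); b <- nlevels(f_b); n <- nlevels(f_s)
  if (any(table(f_s, f_a, f_b) != 1))
    stop("design must be complete and balanced with one value per cell")
  # subjects x cells, cells ordered B within A
  Y <- matrix(NA_real_, n, a * b)
  cell <- (as.integer(f_a) - 1) * b + as.integer(f_b)
  Y[cbind(as.integer(f_s), cell)] <- data[[value]]
  Qa <- orthonormal_contrasts(a)
  Qb <- orthonormal_contrasts(b)
  ja <- rep(1 / sqrt(a), a); jb <- rep(1 / sqrt(b), b)
  effects <- list(
    A = kronecker(Qa, matrix(jb, ncol = 1)),
    B = kronecker(matrix(ja, ncol = 1), Qb),
    `A:B` = kronecker(Qa, Qb))
  out <- lapply(names(effects), function(nm) {
    C <- effects[[nm]]
    Z <- Y %*% C
    q <- ncol(C)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    ss_err <- sum(sweep(Z, 2, zbar)^2)
    # an exactly absent effect leaves numerator and denominator at float
    # noise; report F = 0 rather than a ratio of rounding errors
    tol <- 1e-12 * max(sum((Y - mean(Y))^2), 1)
    F <- if (ss_eff < tol && ss_err < tol) 0 else
      (ss_eff / q) / (ss_err / (q * (n - 1)))
    S <- cov(Z)
    eps <- if (q == 1) 1 else {
      e <- sum(diag(S))^2 / (q * sum(S * S))
      min(1, max(e, 1 / q))
    }
    data.frame(effect = nm, F = F, df1 = q, df2 = q * (n - 1),
               p = pf(F, q, q * (n - 1), lower.tail = FALSE),
               epsilon = eps, df1_gg = eps * q, df2_gg = eps * q * (n - 1),
               p_gg = pf(F, eps * q, eps * q * (n - 1), lower.tail = FALSE))
  })
  res <- do.call(rbind, out)
  names(res)[names(res) == "effect"] <- "effect"
  res$effect <- sub("^A$", factor_a, res$effect)
  res$effect <- sub("^B$", factor_b, res$effect)
  res$effect <- sub("^A:B$", paste(factor_a, factor_b, sep = ":"), res$effect)
  rownames(res) <- NULL
  res
}

#' ROI x adapted-SF repeated-measures ANOVA on median pRF sizes
#'
#' @param medians data frame with `participant`, `roi`, `condition`,
#'   `median_sigma` (one row per cell).
#' @return see [rm_anova_2way()].
#' @export
rm_anova_roi_sf <- function(medians) {
  rm_anova_2way(medians, subject = "participant", factor_a = "roi",
                factor_b = "condition", value = "median_sigma")
}

#' Per-participant condition medians and Mood's tests with FDR
#'
#' For every participant (x ROI), the median pRF size per condition and a
#' Mood's median test of high- vs low-adapted sizes; p-values are
#' Benjamini-Hochberg corrected across the whole family of
#' participant x ROI tests and flagged significant at q < 0.05.
#'
#' @param fits QC-passed rows of a [fit_dataset()] table (columns
#'   `participant`, `roi`, `condition`, `sigma`).
#' @param by_roi split tests by ROI (default) or pool ROIs.
#' @return data frame: participant, roi, medians per condition, the H - L
#'   median difference, `chi2`, `p`, `p_fdr`, `significant`, and
#'   `direction` (+1 when the high-adapted median is larger).
#' @export
group_summary <- function(fits, by_roi = TRUE) {
  if (nrow(fits) == 0) stop("empty fit table")
  roi_f <- if (by_roi) fits$roi else "all"
  groups <- split(fits, list(fits$participant, roi_f), drop = TRUE)
  rows <- lapply(groups, function(g) {
    h <- g$sigma[g$condition == "high_adapted"]
    l <- g$sigma[g$condition == "low_adapted"]
    mt <- moods_median_test(h, l)
    data.frame(participant = g$participant[1],
               roi = if (by_roi) g$roi[1] else "all",
               n_high = length(h), n_low = length(l),
               median_high = median(h), median_low = median(l),
               median_diff = median(h) - median(l),
               chi2 = mt$chi2, p = mt$p)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_fdr < 0.05
  res$direction <- sign(res$median_diff)
  rownames(res) <- NULL
  res[order(res$roi, res$participant), ]
}
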